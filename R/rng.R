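#' Derive a child seed from a top-level seed
#'
#' All randomness in the package flows from a single user-supplied integer
#' seed. Independent consumers (each site, stress mode, optimizer start, ...)
#' receive their own stream seed derived deterministically from the top-level
#' seed and a sequence of keys, so adding a site or a start does not perturb
#' the draws of any other component.
#'
#' The scheme is a multiplicative congruential hash over the integer-coded
#' keys, reduced modulo 2^31 - 1 (all arithmetic stays below 2^53 so the
#' result is exact in double precision on every platform).
#'
#' @param seed Integer top-level seed.
#' @param ... Keys (integers or strings) identifying the consumer.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' split_seed(42, "site", 1, "iS")
split_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- utf8ToInt(k) else k <- as.numeric(k)
    for (v in k) {
      h <- (h * 69069 + (v %% 65536) + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

# Run `code` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
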