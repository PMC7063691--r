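## Evolutionary search with self-adaptation -------------------------------
##
## A (1 + 16) evolution strategy over the seven cultivar traits with
## log-normal step-size self-adaptation, feasibility filtering on yield
## stability (CV <= 10%) and harvest index (<= 0.64), and multi-start from
## randomly scattered parents plus the local cultivar itself.

CV_MAX <- 10
HI_MAX <- 0.64

new_candidate <- function(genome, step_sizes, stats = NULL,
                          feasible = NA) {
  structure(list(genome = genome, step_sizes = step_sizes,
                 stats = stats, feasible = feasible),
            class = "candidate")
}

#' Initial parents for the multi-start search
#'
#' Exactly one parent carries the trait values of the local cultivar; the
#' remaining `n - 1` are scattered uniformly over the trait box. Every
#' parent starts with per-trait mutation step sizes of one tenth of the
#' trait range.
#'
#' @param ranges Trait bounds from [default_trait_ranges()].
#' @param n Number of parents, `>= 1`.
#' @param cultivar A [cultivar_params()] whose traits must lie inside
#'   `ranges`.
#' @param seed Integer seed.
#' @return List of `n` candidates (the cultivar parent first).
#' @export
sample_initial_parents <- function(ranges, n, cultivar, seed) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  lo <- ranges$lower; hi <- ranges$upper
  tr <- cultivar$traits[TRAIT_NAMES]
  if (any(tr < lo | tr > hi)) {
    stop("cultivar traits must lie inside the trait ranges", call. = FALSE)
  }
  step0 <- stats::setNames(0.1 * (hi - lo), TRAIT_NAMES)
  parents <- vector("list", n)
  parents[[1]] <- new_candidate(tr, step0)
  if (n > 1L) {
    with_seed(seed, {
      for (i in 2:n) {
        g <- stats::setNames(lo + stats::runif(length(lo)) * (hi - lo),
                             TRAIT_NAMES)
        parents[[i]] <- new_candidate(g, step0)
      }
    })
  }
  parents
}

# Reflect x into [lo, hi] (repeatedly, for overshoots beyond one width).
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Self-adaptive mutation
#'
#' Each per-trait step size is multiplied by `exp(tau * N(0,1))` with
#' `tau = 1 / sqrt(2 * 7)`, then each trait is perturbed by a Gaussian
#' with its new step size and reflected back into the bounds. Draws come
#' from the current RNG stream; seed the stream for reproducibility.
#'
#' @param parent A candidate (see [sample_initial_parents()]).
#' @param ranges Trait bounds.
#' @return A new unevaluated candidate inside the bounds.
#' @export
mutate_candidate <- function(parent, ranges) {
  tau <- 1 / sqrt(2 * length(TRAIT_NAMES))
  sigma <- parent$step_sizes * exp(tau * stats::rnorm(length(TRAIT_NAMES)))
  g <- parent$genome + sigma * stats::rnorm(length(TRAIT_NAMES))
  g <- reflect_into(g, ranges$lower, ranges$upper)
  new_candidate(stats::setNames(g, TRAIT_NAMES),
                stats::setNames(sigma, TRAIT_NAMES))
}

#' Feasibility of a candidate's yield statistics
#'
#' A candidate is kept in the selection pool only if its yield is stable
#' (coefficient of variation across years at most 10%) and its mean
#' harvest index does not exceed the biological upper limit 0.64.
#'
#' @param stats A [yield_stats()] object.
#' @return `TRUE` if feasible.
#' @export
#' @examples
#' constraint_filter(yield_stats(c(8, 8.2, 8.1), c(0.5, 0.5, 0.5)))
constraint_filter <- function(stats) {
  stats$cv <= CV_MAX && stats$mean_hi <= HI_MAX
}

#' One generation of the (1 + n) evolution strategy
#'
#' Generates `n_candidates` mutants of the parent, evaluates each,
#' discards the infeasible ones, and returns the feasible candidate with
#' the highest mean yield if it strictly beats the parent (ties and
#' near-ties within `tol` go to the parent, for stability); otherwise the
#' parent is returned unchanged. A candidate whose evaluation fails is
#' treated as infeasible.
#'
#' @param parent Evaluated candidate (an unevaluated or infeasible initial
#'   parent is handled: any feasible candidate then wins).
#' @param evaluate Function `genome -> yield_stats`.
#' @param ranges Trait bounds.
#' @param n_candidates Mutants per generation.
#' @param tol Minimum improvement in mean yield (t ha-1) counted as a win.
#' @return The next parent (evaluated, with `feasible` set).
#' @export
easa_generation <- function(parent, evaluate, ranges, n_candidates = 16,
                            tol = 1e-3) {
  parent_fit <- if (!is.null(parent$stats) && isTRUE(parent$feasible)) {
    parent$stats$mean_yield
  } else {
    -Inf
  }
  best <- parent
  best_fit <- parent_fit
  for (k in seq_len(n_candidates)) {
    cand <- mutate_candidate(parent, ranges)
    st <- tryCatch(evaluate(cand$genome), error = function(e) NULL)
    if (is.null(st)) next
    cand$stats <- st
    cand$feasible <- constraint_filter(st)
    if (cand$feasible && st$mean_yield > best_fit + tol) {
      best <- cand
      best_fit <- st$mean_yield
    }
  }
  best
}

# Core multi-start EASA loop over an arbitrary evaluate() function.
# Returns list(best, trace, converged). Used by optimize_ideotype and,
# with stub fitness functions, by the test suite.
easa_optimize <- function(evaluate, parents, ranges, seed,
                          n_candidates = 16, patience = 20, max_gen = 200,
                          tol = 1e-3) {
  n_starts <- length(parents)
  trace <- vector("list", n_starts)
  finals <- vector("list", n_starts)
  converged <- logical(n_starts)
  infeasible_reasons <- c(cv = 0, hi = 0)

  for (s in seq_len(n_starts)) {
    parent <- parents[[s]]
    st <- tryCatch(evaluate(parent$genome), error = function(e) NULL)
    if (!is.null(st)) {
      parent$stats <- st
      parent$feasible <- constraint_filter(st)
      if (!parent$feasible) {
        infeasible_reasons["cv"] <- infeasible_reasons["cv"] +
          (st$cv > CV_MAX)
        infeasible_reasons["hi"] <- infeasible_reasons["hi"] +
          (st$mean_hi > HI_MAX)
      }
    } else {
      parent$feasible <- FALSE
    }
    rows <- list()
    rows[[1]] <- trace_row(s, 0L, parent)
    stall <- 0L
    gen <- 0L
    with_seed(split_seed(seed, "start", s), {
      while (gen < max_gen && stall < patience) {
        gen <- gen + 1L
        fit_before <- if (isTRUE(parent$feasible)) {
          parent$stats$mean_yield
        } else {
          -Inf
        }
        parent <- easa_generation(parent, evaluate, ranges,
                                  n_candidates = n_candidates, tol = tol)
        fit_after <- if (isTRUE(parent$feasible)) {
          parent$stats$mean_yield
        } else {
          -Inf
        }
        if (fit_after > fit_before + tol || (is.infinite(fit_before) &&
                                             is.finite(fit_after))) {
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
        rows[[gen + 1L]] <- trace_row(s, gen, parent)
      }
    })
    converged[s] <- stall >= patience
    trace[[s]] <- do.call(rbind, rows)
    finals[[s]] <- parent
  }

  fits <- vapply(finals, function(p) {
    if (isTRUE(p$feasible)) p$stats$mean_yield else -Inf
  }, numeric(1))
  if (all(is.infinite(fits))) {
    binding <- if (infeasible_reasons["hi"] > infeasible_reasons["cv"]) {
      sprintf("harvest index > %.2f", HI_MAX)
    } else {
      sprintf("yield CV > %.0f%%", CV_MAX)
    }
    stop(sprintf(
      "no feasible candidate found in any start; most often binding constraint: %s",
      binding), call. = FALSE)
  }
  list(best = finals[[which.max(fits)]],
       trace = do.call(rbind, trace),
       converged = converged)
}

trace_row <- function(start, generation, cand) {
  st <- cand$stats
  data.frame(start = start, generation = generation,
             mean_yield = if (is.null(st)) NA_real_ else st$mean_yield,
             cv = if (is.null(st)) NA_real_ else st$cv,
             hi = if (is.null(st)) NA_real_ else st$mean_hi,
             feasible = isTRUE(cand$feasible),
             as.list(cand$genome))
}

#' Design the optimal ideotype for a site
#'
#' Multi-start (1 + `n_candidates`) evolution strategy over the seven
#' traits, maximizing mean yield over the full weather series subject to
#' the stability (CV of yield at most 10%) and harvest-index (at most 0.64)
#' filters. All candidates carry the chosen flowering-stress parameter set
#' (`"iS"` sensitive or `"iT"` tolerant) and the ideotype light-use
#' efficiency multiplier 1.10. Every candidate in every start is evaluated
#' on the identical weather series (common random numbers), so selection
#' differences reflect traits, not weather sampling. One start begins at
#' the local cultivar's traits; the rest are scattered uniformly. A start
#' stops after `patience` generations without improvement greater than
#' `tol`, or at `max_gen`.
#'
#' @param series A `weather_series` (>= 2 years).
#' @param soil A [soil_profile()].
#' @param mgmt A [management()].
#' @param base The local [cultivar_params()] (supplies the cultivar-parent
#'   traits and fixed physiology).
#' @param stress_mode `"iS"` or `"iT"`.
#' @param ranges Trait bounds, default [default_trait_ranges()].
#' @param seed Integer seed driving parent scattering and mutation.
#' @param n_starts Number of initial parents (default 25).
#' @param n_candidates Mutants per generation (default 16).
#' @param patience Improvement-free generations before a start stops.
#' @param max_gen Generation cap per start.
#' @param tol Improvement threshold, t ha-1.
#' @param cfg [crop_config()] constants.
#' @return An object of class `optimization_result`: `best` candidate,
#'   `trace` data frame (`start`, `generation`, `mean_yield`, `cv`, `hi`,
#'   `feasible`, one column per trait), `n_starts`, `converged` (per
#'   start), `stress_mode`.
#' @export
optimize_ideotype <- function(series, soil, mgmt, base,
                              stress_mode = c("iS", "iT"),
                              ranges = default_trait_ranges(), seed = 1,
                              n_starts = 25, n_candidates = 16,
                              patience = 20, max_gen = 200, tol = 1e-3,
                              cfg = crop_config()) {
  stress_mode <- match.arg(stress_mode)
  ideo <- base
  ideo$stress <- stress_params(stress_mode)
  ideo$lue_multiplier <- 1.10

  evaluate <- function(genome) {
    simulate_multi_year(set_traits(ideo, genome), series, soil, mgmt, cfg)
  }
  parents <- sample_initial_parents(ranges, n_starts, base,
                                    split_seed(seed, "parents"))
  res <- easa_optimize(evaluate, parents, ranges, seed,
                       n_candidates = n_candidates, patience = patience,
                       max_gen = max_gen, tol = tol)
  structure(
    list(best = res$best, trace = res$trace, n_starts = n_starts,
         converged = res$converged, stress_mode = stress_mode),
    class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  st <- x$best$stats
  cat(sprintf(
    "<optimization_result> mode %s  %d starts (%d converged)\n  best mean yield %.2f t/ha  CV %.1f%%  HI %.3f\n  traits: %s\n",
    x$stress_mode, x$n_starts, sum(x$converged),
    st$mean_yield, st$cv, st$mean_hi,
    paste(sprintf("%s=%.3g", TRAIT_NAMES, x$best$genome), collapse = " ")))
  invisible(x)
}

#' Write an optimization trace as CSV
#'
#' Columns `start,generation,mean_yield,cv,hi,feasible` plus one column
#' per trait.
#'
#' @param result An `optimization_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
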