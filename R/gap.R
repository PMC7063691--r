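## Genetic yield potential and genetic yield gap --------------------------

#' Genetic yield gap
#'
#' The genetic yield potential of a site is the mean water-limited yield
#' of its optimal ideotype, `y_iw`; the genetic yield gap is the margin of
#' that potential over the current well-adapted cultivar's yield `y_w`:
#' `y_ig_abs = y_iw - y_w` (t ha-1) and `y_ig_pct = 100 * y_ig_abs / y_iw`
#' (% of genetic yield potential). A negative gap (an optimizer run that
#' failed to beat the cultivar) is reported as-is, not clipped.
#'
#' @param y_iw Ideotype (genetic potential) mean yield, t ha-1 (> 0).
#' @param y_w Current-cultivar mean yield, t ha-1.
#' @param mode Optional stress mode label (`"iS"`/`"iT"`).
#' @param site_id Optional site label.
#' @return An object of class `gap_result` with fields `site_id`, `mode`,
#'   `y_w`, `y_iw`, `y_ig_abs`, `y_ig_pct`.
#' @export
#' @examples
#' genetic_yield_gap(12.9, 7.7)  # gap 5.2 t/ha, 40.3% of potential
genetic_yield_gap <- function(y_iw, y_w, mode = NA_character_,
                              site_id = NA_character_) {
  if (!is.finite(y_iw) || y_iw <= 0) {
    stop("y_iw (genetic yield potential) must be > 0", call. = FALSE)
  }
  gap <- y_iw - y_w
  structure(list(site_id = site_id, mode = mode, y_w = y_w, y_iw = y_iw,
                 y_ig_abs = gap, y_ig_pct = 100 * gap / y_iw),
            class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf(
    "<gap_result> %s %s  Y_W %.2f  Y_iW %.2f  gap %.2f t/ha (%.1f%%)\n",
    x$site_id, x$mode, x$y_w, x$y_iw, x$y_ig_abs, x$y_ig_pct))
  invisible(x)
}

#' @export
as.data.frame.gap_result <- function(x, ...) {
  data.frame(site = x$site_id, mode = x$mode, y_w = x$y_w, y_iw = x$y_iw,
             y_ig_abs = x$y_ig_abs, y_ig_pct = x$y_ig_pct)
}

#' Full single-site analysis: cultivar baseline plus both ideotypes
#'
#' Generates (or accepts) the site's weather, simulates the local cultivar
#' under rainfed conditions for the baseline `Y_W`, designs the sensitive
#' (iS) and tolerant (iT) ideotypes on the identical weather series, and
#' assembles a `gap_result` per mode. The baseline cultivar keeps
#' `lue_multiplier = 1`; ideotypes use 1.10.
#'
#' @param site A [site_climate()] object (or preset name).
#' @param base Local [cultivar_params()].
#' @param soil A [soil_profile()].
#' @param seed Top-level seed; weather and each optimization derive their
#'   own streams from it.
#' @param years Weather years to simulate (default 100).
#' @param n_starts,n_candidates,patience,max_gen Optimizer controls, see
#'   [optimize_ideotype()].
#' @param ranges Trait bounds.
#' @param cfg [crop_config()] constants.
#' @param series Optional pre-generated `weather_series` (overrides
#'   `years`); must match the site.
#' @return List with elements `iS` and `iT` (each a `gap_result` carrying
#'   the corresponding `optimization_result` as attribute `"optim"`), plus
#'   `baseline` (the cultivar's [yield_stats()]) and `series`.
#' @export
run_site_analysis <- function(site, base = default_cultivar(),
                              soil = soil_profile(), seed = 1, years = 100,
                              n_starts = 25, n_candidates = 16,
                              patience = 20, max_gen = 200,
                              ranges = default_trait_ranges(),
                              cfg = crop_config(), series = NULL) {
  if (is.character(site)) site <- site_preset(site)
  stopifnot(inherits(site, "site_climate"))
  mgmt <- management_for_site(site)
  if (is.null(series)) {
    series <- generate_weather(site, years,
                               seed = split_seed(seed, site$site_id, "weather"))
  }
  baseline <- simulate_multi_year(base, series, soil, mgmt, cfg)
  out <- list(baseline = baseline, series = series)
  for (mode in c("iS", "iT")) {
    # the same optimizer stream for both modes (common random numbers), so
    # the iT-iS contrast reflects the stress parameterization, not search
    # noise
    opt <- optimize_ideotype(series, soil, mgmt, base, stress_mode = mode,
                             ranges = ranges,
                             seed = split_seed(seed, site$site_id, "optim"),
                             n_starts = n_starts,
                             n_candidates = n_candidates,
                             patience = patience, max_gen = max_gen,
                             cfg = cfg)
    g <- genetic_yield_gap(opt$best$stats$mean_yield, baseline$mean_yield,
                           mode = mode, site_id = site$site_id)
    attr(g, "optim") <- opt
    out[[mode]] <- g
  }
  out
}

#' Aggregate gap results across sites
#'
#' Per-mode arithmetic means of `y_w`, `y_iw`, `y_ig_abs` and `y_ig_pct`
#' across sites, plus the tolerant-versus-sensitive contrast: the absolute
#' difference of the mean gaps and that difference as a percentage of the
#' sensitive-mode mean gap.
#'
#' @param results Data frame with columns `site`, `mode`, `y_w`, `y_iw`,
#'   `y_ig_abs`, `y_ig_pct` (one row per site x mode), or a list of
#'   `gap_result` objects.
#' @return List with `by_mode` (one summary row per mode, grouping label
#'   `"all"`) and `contrast` (`diff_abs` = mean iT gap minus mean iS gap,
#'   t ha-1; `diff_pct` = 100 x that difference over the mean iS gap).
#'   `contrast` is `NULL` unless both modes are present.
#' @export
#' @examples
#' df <- data.frame(site = "s", mode = c("iS", "iT"),
#'                  y_w = 7.7, y_iw = c(11.2, 12.9),
#'                  y_ig_abs = c(3.5, 5.2),
#'                  y_ig_pct = 100 * c(3.5 / 11.2, 5.2 / 12.9))
#' aggregate_gaps(df)
aggregate_gaps <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (NROW(results) == 0L) stop("no gap results to aggregate", call. = FALSE)
  modes <- unique(results$mode)
  by_mode <- do.call(rbind, lapply(modes, function(m) {
    r <- results[results$mode == m, ]
    data.frame(group = "all", mode = m, n_sites = nrow(r),
               y_w = mean(r$y_w), y_iw = mean(r$y_iw),
               y_ig_abs = mean(r$y_ig_abs), y_ig_pct = mean(r$y_ig_pct))
  }))
  contrast <- NULL
  if (all(c("iS", "iT") %in% modes)) {
    gS <- by_mode$y_ig_abs[by_mode$mode == "iS"]
    gT <- by_mode$y_ig_abs[by_mode$mode == "iT"]
    contrast <- data.frame(diff_abs = gT - gS,
                           diff_pct = 100 * (gT - gS) / gS)
  }
  list(by_mode = by_mode, contrast = contrast)
}

#' Round half up to a given number of decimals
#'
#' Printed-precision layer for integer-percent reporting: 48.5 rounds to
#' 49 (unlike [round()]'s round-half-even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
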