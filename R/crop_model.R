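## Daily process-based wheat growth simulation ----------------------------
##
## Structure: thermal-time phenology modified by photoperiod before
## anthesis; canopy expansion with leaf emergence to an A_max ceiling;
## post-anthesis senescence over a stay-green-scaled thermal duration,
## accelerated by water stress; Beer's-law light interception; biomass as
## RUE x intercepted PAR x water-stress index; a single-bucket soil water
## balance with uptake limited by the root-extraction trait; grain number
## set at anthesis and damaged by heat and drought in a short flowering
## window; grain filling from current assimilate plus a labile reserve,
## sink-capped by grain number x potential grain mass.

#' Model configuration constants
#'
#' Numerical constants of the growth model that are not cultivar traits.
#' `n_leaf` final main-stem leaf number; anthesis occurs when cumulative
#' photoperiod-modified thermal time reaches `(n_leaf + booting_leaves) *
#' P_h`. `d_base`/`d_sat` (h) bound the photoperiod response; `f_min` its
#' floor. `sen_dur_base` (deg C d) is the post-anthesis senescence thermal
#' duration of a cultivar with no stay-green expression (`S_G = 0`);
#' `(1 + S_G)` scales it. `transp_per_ipar` (mm per MJ m-2 intercepted PAR)
#' converts interception to transpiration demand. `par_frac` converts
#' global radiation to PAR. `flowering_halfwidth` (days) sets the
#' heat/drought damage window to anthesis +/- that many days.
#'
#' @param ... Named overrides of any constant.
#' @return Named list of constants.
#' @export
crop_config <- function(...) {
  cfg <- list(n_leaf = 9, booting_leaves = 2,
              d_base = 8, d_sat = 15, f_min = 0.25,
              sen_dur_base = 350, transp_per_ipar = 0.45,
              par_frac = 0.5, flowering_halfwidth = 4)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop(sprintf("unknown crop_config constant(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg
}

#' Daily thermal time
#'
#' `max(0, (tmin + tmax)/2 - t_base)`, deg C d.
#'
#' @param tmin,tmax Daily extremes, deg C (`tmax >= tmin`); vectorized.
#' @param t_base Base temperature, deg C.
#' @return Thermal time, deg C d (>= 0).
#' @export
daily_thermal_time <- function(tmin, tmax, t_base = 0) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin", call. = FALSE)
  pmax(0, (tmin + tmax) / 2 - t_base)
}

#' Photoperiod factor on pre-anthesis development
#'
#' Short days slow development in photoperiod-sensitive cultivars:
#' `1 - P_p * max(0, d_sat - daylength) / (d_sat - d_base)`, clamped to
#' `[f_min, 1]`. Days at or above `d_sat` hours impose no delay.
#'
#' @param daylength Hours, in `(0, 24)`; vectorized.
#' @param P_p Photoperiod sensitivity in `[0, 1]`.
#' @param cfg [crop_config()] constants (`d_base`, `d_sat`, `f_min`).
#' @return Development multiplier in `[f_min, 1]`.
#' @export
#' @examples
#' photoperiod_factor(10, 0.7)  # 1 - 0.7 * 5/7 = 0.5
photoperiod_factor <- function(daylength, P_p, cfg = crop_config()) {
  if (P_p < 0 || P_p > 1) stop("P_p must lie in [0, 1]", call. = FALSE)
  f <- 1 - P_p * pmax(0, cfg$d_sat - daylength) / (cfg$d_sat - cfg$d_base)
  pmin(1, pmax(cfg$f_min, f))
}

#' One day of the soil water bucket
#'
#' Precipitation infiltrates; storage above `awc` drains; transpiration is
#' the lesser of demand and the root-limited supply `R_u` x storage after
#' infiltration. The stress index is realized over potential transpiration
#' (1 when there is no demand). Mass balance is exact:
#' `stored_before + precip = stored_after + actual_transp + drainage`.
#'
#' @param stored Water in store at start of day, mm (`<= awc`).
#' @param precip Precipitation, mm.
#' @param pot_transp Transpiration demand, mm.
#' @param R_u Maximum extractable fraction of storage per day, in `(0, 1]`.
#' @param awc Available water capacity, mm.
#' @return List `stored`, `actual_transp`, `drainage`, `stress_index`.
#' @export
soil_water_step <- function(stored, precip, pot_transp, R_u, awc) {
  if (stored < 0 || precip < 0 || pot_transp < 0 || R_u < 0 || awc <= 0) {
    stop("soil_water_step inputs must be non-negative (awc > 0)",
         call. = FALSE)
  }
  if (stored > awc) stop("stored must not exceed awc", call. = FALSE)
  filled <- stored + precip
  drainage <- max(0, filled - awc)
  filled <- filled - drainage
  actual <- min(pot_transp, R_u * filled)
  list(stored = filled - actual,
       actual_transp = actual,
       drainage = drainage,
       stress_index = if (pot_transp > 0) actual / pot_transp else 1)
}

#' Heat-induced grain-number reduction over the flowering window
#'
#' Each window day with a maximum temperature above the threshold `HSGNT`
#' removes `HSGNR` of potential grain number per degree of exceedance;
#' daily damages accumulate and the total is capped at 1.
#'
#' @param window_tmax Daily maximum temperatures over the window, deg C.
#' @param HSGNT Threshold temperature, deg C.
#' @param HSGNR Reduction rate, fraction per deg C per day.
#' @return Fraction of grain number lost, in `[0, 1]`.
#' @export
heat_stress_gn_reduction <- function(window_tmax, HSGNT, HSGNR) {
  if (length(window_tmax) == 0L) {
    stop("flowering window must be non-empty", call. = FALSE)
  }
  min(1, sum(HSGNR * pmax(0, window_tmax - HSGNT)))
}

#' Drought-induced grain-number reduction over the flowering window
#'
#' Each window day with a water-stress index below the threshold `DSGNT`
#' removes `DSGNS` of potential grain number per unit of shortfall; the
#' accumulated total is capped at `DSGNRMax`.
#'
#' @param window_stress Daily stress indices over the window, in `[0, 1]`.
#' @param DSGNT Stress-index threshold in `[0, 1]`.
#' @param DSGNS Sensitivity, fraction per unit stress per day.
#' @param DSGNRMax Cap on the total reduction, in `[0, 1]`.
#' @return Fraction of grain number lost, in `[0, DSGNRMax]`.
#' @export
drought_stress_gn_reduction <- function(window_stress, DSGNT, DSGNS,
                                        DSGNRMax) {
  if (length(window_stress) == 0L) {
    stop("flowering window must be non-empty", call. = FALSE)
  }
  if (any(window_stress < 0 | window_stress > 1)) {
    stop("stress indices must lie in [0, 1]", call. = FALSE)
  }
  min(DSGNRMax, sum(DSGNS * pmax(0, DSGNT - window_stress)))
}

#' Water-stress acceleration of leaf senescence
#'
#' Linear in the stress shortfall: `1 + (W_ss - 1) * (1 - stress_index)`.
#' Multiplies the post-anthesis senescence rate, so a fully stressed
#' canopy (`stress_index = 0`) senesces `W_ss` times faster.
#'
#' @param stress_index Daily water-stress index in `[0, 1]`.
#' @param W_ss Maximum multiplier, `>= 1`.
#' @return Multiplier in `[1, W_ss]`.
#' @export
senescence_multiplier <- function(stress_index, W_ss) {
  if (W_ss < 1) stop("W_ss must be >= 1", call. = FALSE)
  if (any(stress_index < 0 | stress_index > 1)) {
    stop("stress_index must lie in [0, 1]", call. = FALSE)
  }
  1 + (W_ss - 1) * (1 - stress_index)
}

#' Simulate one cropping season
#'
#' Runs the daily loop from sowing (the first row of `weather`) to
#' maturity. See the package vignette for the full model description.
#'
#' @param cv A [cultivar_params()] object.
#' @param weather A `weather_series` slice whose first row is the sowing
#'   day, with at least 365 rows and a `doy` column.
#' @param soil A [soil_profile()].
#' @param mgmt A [management()] (supplies latitude for day length).
#' @param cfg [crop_config()] constants.
#' @return An object of class `season_result`: `yield` and `biomass`
#'   (t ha-1), `hi`, `anthesis_das` and `maturity_das` (days after
#'   sowing), `grain_fill_days`, `cum_ipar` (MJ m-2), `grain_number`
#'   (grains m-2), `grain_wt` (mg), and a `water` list with the season
#'   water-balance components (mm).
#' @export
#' @examples
#' site <- site_preset("temperate_CW")
#' w <- generate_weather(site, 2, seed = 1)
#' season <- w[site$sowing_doy + 0:364, ]
#' simulate_season(default_cultivar(), season, soil_profile(),
#'                 management_for_site(site))
simulate_season <- function(cv, weather, soil, mgmt, cfg = crop_config()) {
  stopifnot(inherits(cv, "cultivar_params"), inherits(soil, "soil_profile"),
            inherits(mgmt, "management"))
  tmin <- weather$tmin; tmax <- weather$tmax
  precip <- weather$precip; rad <- weather$rad
  n <- length(tmin)
  if (n < 365L) {
    stop("weather slice must cover at least 365 days from sowing",
         call. = FALSE)
  }
  if (anyNA(tmin) || anyNA(tmax) || anyNA(precip) || anyNA(rad) ||
      any(!is.finite(tmin)) || any(!is.finite(tmax)) ||
      any(!is.finite(precip)) || any(!is.finite(rad))) {
    stop("weather contains non-finite values", call. = FALSE)
  }
  if (any(tmax < tmin)) stop("weather has tmax < tmin", call. = FALSE)

  tr <- cv$traits; st <- cv$stress
  A_max <- tr[["A_max"]]; S_G <- tr[["S_G"]]; P_h <- tr[["P_h"]]
  G_f <- tr[["G_f"]]; R_u <- tr[["R_u"]]; W_ss <- tr[["W_ss"]]
  rue_eff <- cv$rue * cv$lue_multiplier
  k_ext <- cv$k_ext
  par_frac <- cfg$par_frac; tpi <- cfg$transp_per_ipar
  awc <- soil$awc

  tt <- daily_thermal_time(tmin, tmax, cv$t_base)
  dl <- day_length(mgmt$latitude, weather$doy)
  pf <- photoperiod_factor(dl, tr[["P_p"]], cfg)
  tt_mod <- tt * pf

  tt_anth <- (cfg$n_leaf + cfg$booting_leaves) * P_h
  tt_leaf_full <- cfg$n_leaf * P_h
  sen_dur <- cfg$sen_dur_base * (1 + S_G)

  stored <- soil$initial_fill * awc
  stored0 <- stored
  biomass <- 0; cum_tt <- 0; cum_ipar <- 0
  post_tt <- 0; sen_tt <- 0
  anthesis_day <- NA_integer_; anth_biomass <- NA_real_
  maturity_day <- n
  sum_transp <- 0; sum_drain <- 0; sum_precip <- 0
  stress_vec <- numeric(n)
  phase <- 1L

  for (d in seq_len(n)) {
    lai <- if (phase == 1L) {
      A_max * min(1, cum_tt / tt_leaf_full)
    } else {
      A_max * max(0, 1 - sen_tt / sen_dur)
    }
    ipar <- par_frac * rad[d] * (1 - exp(-k_ext * lai))
    pot_transp <- tpi * ipar

    # soil bucket (same arithmetic as soil_water_step, inlined)
    filled <- stored + precip[d]
    drain <- max(0, filled - awc)
    filled <- filled - drain
    transp <- min(pot_transp, R_u * filled)
    stored <- filled - transp
    si <- if (pot_transp > 0) transp / pot_transp else 1
    stress_vec[d] <- si
    sum_transp <- sum_transp + transp
    sum_drain <- sum_drain + drain
    sum_precip <- sum_precip + precip[d]

    biomass <- biomass + rue_eff * ipar * si
    cum_ipar <- cum_ipar + ipar

    if (phase == 1L) {
      cum_tt <- cum_tt + tt_mod[d]
      if (cum_tt >= tt_anth) {
        phase <- 2L
        anthesis_day <- d
        anth_biomass <- biomass
      }
    } else {
      post_tt <- post_tt + tt[d]
      sen_tt <- sen_tt + tt[d] * (1 + (W_ss - 1) * (1 - si))
      if (post_tt >= G_f || sen_tt >= sen_dur) {
        maturity_day <- d
        break
      }
    }
  }

  if (is.na(anthesis_day)) {
    # season too cold/short to flower: no grain
    res <- list(yield = 0, biomass = biomass / 100, hi = 0,
                anthesis_das = NA_integer_, maturity_das = n,
                grain_fill_days = 0L, cum_ipar = cum_ipar,
                grain_number = 0, grain_wt = 0)
  } else {
    hw <- cfg$flowering_halfwidth
    win <- max(1L, anthesis_day - hw):min(maturity_day, anthesis_day + hw)
    heat_red <- heat_stress_gn_reduction(tmax[win], st[["HSGNT"]],
                                         st[["HSGNR"]])
    drought_red <- drought_stress_gn_reduction(stress_vec[win],
                                               st[["DSGNT"]], st[["DSGNS"]],
                                               st[["DSGNRMax"]])
    grain_number <- cv$grains_per_g * anth_biomass *
      (1 - heat_red) * (1 - drought_red)

    fill_frac <- min(1, post_tt / G_f)
    supply <- (biomass - anth_biomass) +
      cv$labile_frac * anth_biomass * fill_frac
    sink_cap <- grain_number * cv$max_grain_wt / 1000  # mg -> g m-2
    yield_g <- min(supply, sink_cap)
    res <- list(
      yield = yield_g / 100,          # g m-2 -> t ha-1
      biomass = biomass / 100,
      hi = if (biomass > 0) yield_g / biomass else 0,
      anthesis_das = anthesis_day,
      maturity_das = maturity_day,
      grain_fill_days = maturity_day - anthesis_day,
      cum_ipar = cum_ipar,
      grain_number = grain_number,
      grain_wt = if (grain_number > 0) yield_g / grain_number * 1000 else 0)
  }
  res$water <- list(initial = stored0, final = stored,
                    precip = sum_precip, transp = sum_transp,
                    drainage = sum_drain)
  class(res) <- "season_result"
  res
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf(
    "<season_result> yield %.2f t/ha  biomass %.2f t/ha  HI %.3f\n  anthesis das %s  maturity das %d  grain fill %d d  IPAR %.0f MJ/m2\n",
    x$yield, x$biomass, x$hi,
    if (is.na(x$anthesis_das)) "NA" else x$anthesis_das,
    x$maturity_das, x$grain_fill_days, x$cum_ipar))
  invisible(x)
}

#' Multi-year yield statistics
#'
#' Assembles per-year yields and harvest indices into the statistics the
#' optimizer consumes. The coefficient of variation uses the sample
#' standard deviation (divisor n - 1, as [stats::sd()]); this convention
#' is fixed so the 10% yield-stability filter is reproducible.
#'
#' @param yields Per-year yields, t ha-1 (length >= 2).
#' @param his Per-year harvest indices (same length).
#' @param per_year Optional list of `season_result` objects.
#' @return An object of class `yield_stats`: `mean_yield`, `cv` (%),
#'   `mean_hi`, `n_years`, `per_year`.
#' @export
#' @examples
#' yield_stats(c(8, 10, 12), c(0.5, 0.5, 0.5))  # mean 10, cv 20
yield_stats <- function(yields, his, per_year = NULL) {
  if (length(yields) < 2L) {
    stop("yield statistics require at least 2 years (CV undefined otherwise)",
         call. = FALSE)
  }
  m <- mean(yields)
  structure(
    list(mean_yield = m,
         cv = if (m > 0) 100 * stats::sd(yields) / m else 0,
         mean_hi = mean(his),
         n_years = length(yields),
         per_year = per_year),
    class = "yield_stats")
}

#' @export
#' @rdname yield_stats
#' @param x A `yield_stats` object.
#' @param ... Unused.
as.data.frame.yield_stats <- function(x, ...) {
  if (is.null(x$per_year)) {
    stop("no per-season results attached to these yield statistics",
         call. = FALSE)
  }
  rows <- lapply(seq_along(x$per_year), function(y) {
    r <- x$per_year[[y]]
    data.frame(year = y, yield = r$yield, biomass = r$biomass, hi = r$hi,
               anthesis_das = r$anthesis_das, maturity_das = r$maturity_das,
               grain_fill_days = r$grain_fill_days, cum_ipar = r$cum_ipar,
               grain_number = r$grain_number, grain_wt = r$grain_wt)
  })
  do.call(rbind, rows)
}

#' @export
print.yield_stats <- function(x, ...) {
  cat(sprintf(
    "<yield_stats> %d years  mean yield %.2f t/ha  CV %.1f%%  mean HI %.3f\n",
    x$n_years, x$mean_yield, x$cv, x$mean_hi))
  invisible(x)
}

#' Simulate every season of a multi-year weather series
#'
#' One season per weather year: season `y` starts at the sowing day of
#' year `y` and runs 365 days, borrowing the start of the following year
#' (cyclically, for the final year) to complete the season. The soil store
#' is re-initialized at each sowing, so years are independent.
#'
#' @param cv A [cultivar_params()].
#' @param series A `weather_series` covering `>= 2` years.
#' @param soil A [soil_profile()].
#' @param mgmt A [management()]; its `sowing_doy` places each season.
#' @param cfg [crop_config()] constants.
#' @return A [yield_stats()] object with one `season_result` per year.
#' @export
simulate_multi_year <- function(cv, series, soil, mgmt,
                                cfg = crop_config()) {
  n <- NROW(series)
  years <- n %/% 365L
  if (years < 2L) {
    stop("need at least 2 weather years (CV undefined otherwise)",
         call. = FALSE)
  }
  doy <- series$doy
  seasons <- vector("list", years)
  for (y in seq_len(years)) {
    start <- (y - 1L) * 365L + mgmt$sowing_doy
    idx <- ((start + 0:364 - 1L) %% n) + 1L
    slice <- list(tmin = series$tmin[idx], tmax = series$tmax[idx],
                  precip = series$precip[idx], rad = series$rad[idx],
                  doy = doy[idx])
    seasons[[y]] <- simulate_season(cv, slice, soil, mgmt, cfg)
  }
  yield_stats(vapply(seasons, `[[`, numeric(1), "yield"),
              vapply(seasons, `[[`, numeric(1), "hi"),
              per_year = seasons)
}
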