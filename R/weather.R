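## Stochastic daily weather generation -----------------------------------
##
## A WGEN-style generator: monthly two-state Markov chain for wet/dry
## occurrence, exponential wet-day amounts, AR(1) temperature residuals
## around a smooth seasonal curve, and radiation conditioned on wet/dry
## state. It is a climate *sampler* -- it reproduces the first-order
## statistics (monthly means, wet-day persistence, inter-annual
## variability, dry and heat spells) that drive a rainfed crop simulation,
## not the full distributional machinery of an observational generator.

# 365-day calendar, no leap days.
MONTH_LEN <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_OF_DOY <- rep.int(seq_len(12), MONTH_LEN)
MID_MONTH_DOY <- cumsum(MONTH_LEN) - MONTH_LEN / 2

#' Construct a synthetic site climate description
#'
#' Bundles the monthly statistics that parameterize the weather generator
#' for one site: temperature means and variability, precipitation occurrence
#' (first-order two-state Markov chain) and wet-day amounts, and daily global
#' radiation, plus the latitude (for day length) and the local sowing date.
#'
#' @param site_id Short site label.
#' @param latitude Degrees north, in `[-67, 67]`.
#' @param monthly_tmin_mean,monthly_tmax_mean Monthly mean daily minimum and
#'   maximum temperature, deg C (12 values each).
#' @param monthly_t_sd Monthly standard deviation of the daily temperature
#'   anomaly, deg C (12 values).
#' @param monthly_rad_mean Monthly mean daily global radiation,
#'   MJ m-2 day-1 (12 values).
#' @param p_wet_given_wet,p_wet_given_dry Monthly transition probabilities of
#'   the wet/dry occurrence chain (12 values each, in `[0, 1]`).
#' @param wet_day_precip_mean Monthly mean precipitation on wet days, mm
#'   (12 values).
#' @param sowing_doy Day of year of sowing for the local cultivar.
#' @return An object of class `site_climate`.
#' @seealso [site_preset()] for shipped archetypes, [generate_weather()].
#' @export
site_climate <- function(site_id, latitude,
                         monthly_tmin_mean, monthly_tmax_mean, monthly_t_sd,
                         monthly_rad_mean,
                         p_wet_given_wet, p_wet_given_dry,
                         wet_day_precip_mean, sowing_doy) {
  for (nm in c("monthly_tmin_mean", "monthly_tmax_mean", "monthly_t_sd",
               "monthly_rad_mean", "p_wet_given_wet", "p_wet_given_dry",
               "wet_day_precip_mean")) {
    v <- get(nm)
    if (length(v) != 12L || !is.numeric(v) || anyNA(v)) {
      stop(sprintf("'%s' must be 12 finite numeric values", nm), call. = FALSE)
    }
  }
  if (abs(latitude) > 67) {
    stop("latitude must lie in [-67, 67] so day length is defined year-round",
         call. = FALSE)
  }
  if (any(monthly_tmax_mean < monthly_tmin_mean)) {
    stop("monthly_tmax_mean must be >= monthly_tmin_mean for every month",
         call. = FALSE)
  }
  if (any(p_wet_given_wet < 0 | p_wet_given_wet > 1) ||
      any(p_wet_given_dry < 0 | p_wet_given_dry > 1)) {
    stop("occurrence probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(wet_day_precip_mean < 0)) {
    stop("wet_day_precip_mean must be >= 0", call. = FALSE)
  }
  if (any(monthly_rad_mean <= 0)) {
    stop("monthly_rad_mean must be > 0", call. = FALSE)
  }
  if (any(monthly_t_sd < 0)) stop("monthly_t_sd must be >= 0", call. = FALSE)
  sowing_doy <- as.integer(sowing_doy)
  if (sowing_doy < 1L || sowing_doy > 365L) {
    stop("sowing_doy must be in [1, 365]", call. = FALSE)
  }
  structure(
    list(site_id = as.character(site_id), latitude = as.numeric(latitude),
         monthly_tmin_mean = as.numeric(monthly_tmin_mean),
         monthly_tmax_mean = as.numeric(monthly_tmax_mean),
         monthly_t_sd = as.numeric(monthly_t_sd),
         monthly_rad_mean = as.numeric(monthly_rad_mean),
         p_wet_given_wet = as.numeric(p_wet_given_wet),
         p_wet_given_dry = as.numeric(p_wet_given_dry),
         wet_day_precip_mean = as.numeric(wet_day_precip_mean),
         sowing_doy = sowing_doy),
    class = "site_climate")
}

#' @export
print.site_climate <- function(x, ...) {
  imp <- implied_climate(x)
  cat(sprintf(
    "<site_climate> %s  lat %.1fN  sowing doy %d\n  implied annual: T %.1f C, precip %.0f mm, rad %.1f MJ m-2 d-1\n",
    x$site_id, x$latitude, x$sowing_doy,
    imp["annual_t"], imp["annual_precip"], imp["mean_rad"]))
  invisible(x)
}

# Stationary wet-day probability of the monthly occurrence chain.
stationary_wet_prob <- function(site) {
  p11 <- site$p_wet_given_wet
  p01 <- site$p_wet_given_dry
  ifelse(p01 + (1 - p11) <= 0, 0, p01 / (1 + p01 - p11))
}

#' Annual climate implied by a site parameterization
#'
#' Closed-form annual means implied by the monthly parameters: expected
#' annual precipitation follows from the stationary wet-day probability of
#' the occurrence chain times the wet-day mean amount, temperature and
#' radiation from month-length-weighted monthly means.
#'
#' @param site A [site_climate()] object.
#' @return Named vector `annual_t` (deg C), `annual_precip` (mm yr-1),
#'   `mean_rad` (MJ m-2 day-1), `wet_fraction`.
#' @export
implied_climate <- function(site) {
  stopifnot(inherits(site, "site_climate"))
  pw <- stationary_wet_prob(site)
  c(annual_t = sum(MONTH_LEN * (site$monthly_tmin_mean + site$monthly_tmax_mean) / 2) / 365,
    annual_precip = sum(MONTH_LEN * pw * site$wet_day_precip_mean),
    mean_rad = sum(MONTH_LEN * site$monthly_rad_mean) / 365,
    wet_fraction = sum(MONTH_LEN * pw) / 365)
}

# Builds a site from annual targets and seasonal shapes, then rescales so the
# implied annual temperature, precipitation and radiation hit the targets
# exactly (additive shift for T, multiplicative for precip and rad).
make_archetype <- function(site_id, latitude, annual_t, t_amplitude,
                           diurnal_range, t_sd_winter, t_sd_summer,
                           annual_precip, winter_precip_weight,
                           mean_rad, rad_amplitude,
                           p_ww, p_wd, sowing_doy) {
  m <- seq_len(12)
  season <- cos(2 * pi * (m - 7) / 12)  # +1 in July, -1 in January
  tmid <- annual_t + t_amplitude * season  # warm peak in July
  tmid <- tmid + (annual_t - sum(MONTH_LEN * tmid) / 365)
  t_sd <- t_sd_winter + (t_sd_summer - t_sd_winter) * (1 + season) / 2
  # winter_precip_weight > 0 concentrates wet-day amounts in winter months
  wshape <- 1 - winter_precip_weight * season
  wshape[wshape < 0.1] <- 0.1
  pw <- ifelse(p_wd + (1 - p_ww) <= 0, 0, p_wd / (1 + p_wd - p_ww))
  wet_mean <- wshape / sum(MONTH_LEN * pw * wshape) * annual_precip
  radm <- mean_rad + rad_amplitude * season
  radm <- radm * mean_rad / (sum(MONTH_LEN * radm) / 365)
  radm[radm < 0.5] <- 0.5
  site_climate(
    site_id = site_id, latitude = latitude,
    monthly_tmin_mean = tmid - diurnal_range / 2,
    monthly_tmax_mean = tmid + diurnal_range / 2,
    monthly_t_sd = t_sd,
    monthly_rad_mean = radm,
    p_wet_given_wet = rep(p_ww, 12), p_wet_given_dry = rep(p_wd, 12),
    wet_day_precip_mean = wet_mean, sowing_doy = sowing_doy)
}

WEATHER_PRESETS <- list(
  # Archetypes spanning the European wheat-belt climate gradient: annual
  # mean temperature 7.1-19.2 C, precipitation 344-801 mm yr-1, mean daily
  # radiation 9.7-17.0 MJ m-2 day-1. They are synthetic constructions, not
  # reconstructions of particular stations.
  cool_wet_NW = list(site_id = "cool_wet_NW", latitude = 55, annual_t = 7.1,
                     t_amplitude = 6, diurnal_range = 7,
                     t_sd_winter = 3.5, t_sd_summer = 2.5,
                     annual_precip = 801, winter_precip_weight = -0.25,
                     mean_rad = 9.7, rad_amplitude = 7.5,
                     p_ww = 0.65, p_wd = 0.35, sowing_doy = 258),
  temperate_CW = list(site_id = "temperate_CW", latitude = 50, annual_t = 10.4,
                      t_amplitude = 7, diurnal_range = 8,
                      t_sd_winter = 3.5, t_sd_summer = 3.0,
                      annual_precip = 690, winter_precip_weight = -0.20,
                      mean_rad = 11.5, rad_amplitude = 8.5,
                      p_ww = 0.60, p_wd = 0.30, sowing_doy = 289),
  continental_CE = list(site_id = "continental_CE", latitude = 47,
                        annual_t = 10.9, t_amplitude = 10, diurnal_range = 9,
                        t_sd_winter = 4.0, t_sd_summer = 3.2,
                        annual_precip = 560, winter_precip_weight = 0.15,
                        mean_rad = 12.8, rad_amplitude = 9.0,
                        p_ww = 0.55, p_wd = 0.25, sowing_doy = 280),
  cold_NE = list(site_id = "cold_NE", latitude = 59, annual_t = 7.4,
                 t_amplitude = 11, diurnal_range = 8,
                 t_sd_winter = 5.0, t_sd_summer = 3.0,
                 annual_precip = 540, winter_precip_weight = 0.10,
                 mean_rad = 10.6, rad_amplitude = 8.2,
                 p_ww = 0.60, p_wd = 0.28, sowing_doy = 250),
  hot_dry_SW = list(site_id = "hot_dry_SW", latitude = 39, annual_t = 19.2,
                    t_amplitude = 8, diurnal_range = 11,
                    t_sd_winter = 3.0, t_sd_summer = 3.5,
                    annual_precip = 344, winter_precip_weight = 0.85,
                    mean_rad = 17.0, rad_amplitude = 9.5,
                    p_ww = 0.45, p_wd = 0.12, sowing_doy = 320)
)

#' Shipped site climate archetypes
#'
#' Five synthetic archetypes spanning the climate gradient of the European
#' wheat belt. Their implied annual means (see [implied_climate()]) lie
#' within, and at the family extremes exactly on, the ranges
#' 7.1-19.2 deg C mean annual temperature, 344-801 mm annual precipitation
#' and 9.7-17.0 MJ m-2 day-1 mean daily radiation: `cool_wet_NW` is the
#' coolest and wettest with the dullest skies, `hot_dry_SW` the hottest and
#' driest with the strongest radiation.
#'
#' @param name One of `"cool_wet_NW"`, `"temperate_CW"`, `"continental_CE"`,
#'   `"cold_NE"`, `"hot_dry_SW"`.
#' @return A [site_climate()] object.
#' @export
#' @examples
#' implied_climate(site_preset("hot_dry_SW"))
site_preset <- function(name) {
  if (length(name) != 1L || !name %in% names(WEATHER_PRESETS)) {
    stop(sprintf("unknown site preset '%s'; available presets: %s",
                 as.character(name)[1],
                 paste(names(WEATHER_PRESETS), collapse = ", ")),
         call. = FALSE)
  }
  do.call(make_archetype, WEATHER_PRESETS[[name]])
}

# Smooth daily curve through 12 monthly values: single annual harmonic
# fitted by least squares at mid-month days.
harmonic_daily <- function(monthly) {
  ang <- 2 * pi * MID_MONTH_DOY / 365
  X <- cbind(1, cos(ang), sin(ang))
  beta <- solve(crossprod(X), crossprod(X, monthly))
  angd <- 2 * pi * seq_len(365) / 365
  as.numeric(cbind(1, cos(angd), sin(angd)) %*% beta)
}

#' Generate a synthetic multi-year daily weather series
#'
#' Simulates `years` x 365 days of tmin/tmax, precipitation and global
#' radiation from a [site_climate()] parameterization. Wet/dry occurrence
#' follows the monthly two-state Markov chain; wet-day amounts are
#' exponential with the monthly mean; daily temperatures follow a smooth
#' seasonal harmonic plus an AR(1) anomaly shared between tmin and tmax;
#' radiation varies log-normally around the seasonal mean and is reduced by
#' the factor `wet_rad_factor` on wet days, with dry days brightened so the
#' monthly expectation stays at the configured mean.
#'
#' @param site A [site_climate()] object.
#' @param years Number of 365-day years, `>= 1`.
#' @param seed Integer seed; identical `(site, years, seed)` give an
#'   identical series.
#' @param t_autocorr Lag-1 autocorrelation of the temperature anomaly.
#' @param wet_rad_factor Radiation multiplier on wet days (cloud coupling).
#' @param rad_cv Log-scale SD of the daily radiation multiplier.
#' @return A `weather_series`: a data frame with columns `day`, `doy`,
#'   `tmin`, `tmax` (deg C), `precip` (mm), `rad` (MJ m-2 day-1) and
#'   attributes `site`, `years`, `seed`.
#' @export
#' @examples
#' w <- generate_weather(site_preset("temperate_CW"), years = 3, seed = 1)
#' summarize_climate(w)
generate_weather <- function(site, years, seed, t_autocorr = 0.7,
                             wet_rad_factor = 0.75, rad_cv = 0.22) {
  stopifnot(inherits(site, "site_climate"))
  years <- as.integer(years)
  if (is.na(years) || years < 1L) stop("years must be >= 1", call. = FALSE)
  n <- years * 365L
  doy <- rep.int(seq_len(365L), years)
  mon <- MONTH_OF_DOY[doy]

  tmin_seas <- harmonic_daily(site$monthly_tmin_mean)[doy]
  tmax_seas <- harmonic_daily(site$monthly_tmax_mean)[doy]
  rad_seas <- harmonic_daily(site$monthly_rad_mean)[doy]
  rad_seas[rad_seas < 0.2] <- 0.2
  t_sd <- site$monthly_t_sd[mon]

  pw_stat <- stationary_wet_prob(site)
  # dry-day brightening that compensates the wet-day reduction so the
  # expected radiation stays at the configured monthly mean
  dry_mult <- 1 / ((1 - pw_stat) + wet_rad_factor * pw_stat)

  with_seed(seed, {
    u <- stats::runif(n)
    wet <- logical(n)
    p11 <- site$p_wet_given_wet
    p01 <- site$p_wet_given_dry
    prev <- u[1] < pw_stat[mon[1]]  # stationary start
    wet[1] <- prev
    for (i in 2:n) {
      p <- if (prev) p11[mon[i]] else p01[mon[i]]
      prev <- u[i] < p
      wet[i] <- prev
    }
    precip <- numeric(n)
    nwet <- sum(wet)
    if (nwet > 0) {
      mu <- site$wet_day_precip_mean[mon[wet]]
      precip[wet] <- ifelse(mu > 0, stats::rexp(nwet) * mu, 0)
    }
    z <- stats::rnorm(n)
    anom <- numeric(n)
    a <- t_autocorr
    innov_scale <- sqrt(1 - a^2)
    anom[1] <- z[1] * t_sd[1]
    for (i in 2:n) anom[i] <- a * anom[i - 1] + innov_scale * t_sd[i] * z[i]
    tmin <- tmin_seas + anom
    tmax <- tmax_seas + anom
    rad_mult <- exp(rad_cv * stats::rnorm(n) - rad_cv^2 / 2)
    rad <- rad_seas * dry_mult[mon] * ifelse(wet, wet_rad_factor, 1) * rad_mult
  })

  out <- data.frame(day = seq_len(n), doy = doy, tmin = tmin, tmax = tmax,
                    precip = precip, rad = rad)
  attr(out, "site") <- site
  attr(out, "years") <- years
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("weather_series", "data.frame")
  out
}

#' Summary climate statistics of a weather series
#'
#' @param series A `weather_series` from [generate_weather()] or
#'   [read_weather_csv()].
#' @return Named vector: `mean_annual_t` (deg C), `annual_precip`
#'   (mm yr-1, total divided by the number of years), `mean_rad`
#'   (MJ m-2 day-1), `wet_fraction` (share of days with precip > 0).
#' @export
summarize_climate <- function(series) {
  if (NROW(series) == 0L) stop("empty weather series", call. = FALSE)
  yrs <- NROW(series) / 365
  c(mean_annual_t = mean((series$tmin + series$tmax) / 2),
    annual_precip = sum(series$precip) / yrs,
    mean_rad = mean(series$rad),
    wet_fraction = mean(series$precip > 0))
}

#' Astronomical day length
#'
#' Hours between sunrise and sunset from standard solar-declination
#' geometry (declination `23.45 sin(2 pi (284 + doy) / 365)` degrees).
#'
#' @param latitude Degrees north, `|latitude| <= 67`.
#' @param doy Day of year (1-365); vectorized.
#' @return Day length in hours, in `(0, 24)`.
#' @export
#' @examples
#' day_length(52, 172)  # around the June solstice
day_length <- function(latitude, doy) {
  if (abs(latitude) > 67) {
    stop("day_length is only defined for |latitude| <= 67", call. = FALSE)
  }
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  lat <- latitude * pi / 180
  cos_h <- -tan(lat) * tan(decl)
  cos_h <- pmin(1, pmax(-1, cos_h))
  24 / pi * acos(cos_h)
}

#' Write / read a daily weather series as CSV
#'
#' Columns `day,tmin,tmax,precip,rad` (units deg C, mm, MJ m-2 day-1),
#' one header line, one row per day.
#'
#' @param series A `weather_series` data frame.
#' @param path File path.
#' @return `write_weather_csv` returns `path` invisibly; `read_weather_csv`
#'   returns a `weather_series` data frame (site metadata is not stored in
#'   the CSV and is absent after a round trip).
#' @export
write_weather_csv <- function(series, path) {
  utils::write.csv(
    series[, c("day", "tmin", "tmax", "precip", "rad")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("day", "tmin", "tmax", "precip", "rad")
  if (!all(need %in% names(df))) {
    stop("weather CSV must have columns day,tmin,tmax,precip,rad",
         call. = FALSE)
  }
  if (any(df$tmax < df$tmin) || any(df$precip < 0) || any(df$rad < 0)) {
    stop("weather CSV violates physical bounds (tmax >= tmin, precip >= 0, rad >= 0)",
         call. = FALSE)
  }
  df$doy <- (df$day - 1L) %% 365L + 1L
  class(df) <- c("weather_series", "data.frame")
  attr(df, "years") <- NROW(df) / 365
  df
}
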