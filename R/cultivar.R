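## Cultivar parameterization ----------------------------------------------

#' Names of the seven optimizable cultivar traits
#'
#' `A_max` potential maximum leaf area index (dimensionless LAI);
#' `S_G` stay-green factor scaling post-anthesis senescence duration;
#' `P_h` phyllochron (deg C d per leaf); `P_p` photoperiod sensitivity
#' (0 = insensitive, 1 = maximal); `G_f` grain-filling thermal duration
#' (deg C d); `R_u` maximum fraction of stored soil water extractable per
#' day (day-1); `W_ss` maximum senescence acceleration under full water
#' stress (dimensionless multiplier, >= 1).
#'
#' @export
TRAIT_NAMES <- c("A_max", "S_G", "P_h", "P_p", "G_f", "R_u", "W_ss")

STRESS_NAMES <- c("HSGNT", "HSGNR", "DSGNT", "DSGNS", "DSGNRMax")

#' Bounds of the trait search space
#'
#' Default lower/upper bounds for the seven optimizable traits. They stand
#' in for a calibration table and are deliberately wide: 0.5-2 times a
#' reference canopy for `A_max`, the full `[0, 1]` photoperiod-sensitivity
#' scale, phyllochron and grain-filling durations spanning modern cultivar
#' variation, and root-uptake / senescence-acceleration ranges bracketing
#' conservative and profligate water-use strategies. All are calibration
#' knobs, overridable per call.
#'
#' @param ... Named `c(lower, upper)` overrides, e.g. `P_h = c(80, 120)`.
#' @return A data frame with rownames [TRAIT_NAMES] and columns `lower`,
#'   `upper`.
#' @export
#' @examples
#' default_trait_ranges(G_f = c(500, 800))
default_trait_ranges <- function(...) {
  r <- data.frame(
    lower = c(A_max = 2.25, S_G = 0, P_h = 70, P_p = 0, G_f = 400,
              R_u = 0.02, W_ss = 1),
    upper = c(A_max = 9.0, S_G = 2, P_h = 140, P_p = 1, G_f = 900,
              R_u = 0.12, W_ss = 4))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% TRAIT_NAMES) {
      stop(sprintf("unknown trait '%s'; traits are: %s", nm,
                   paste(TRAIT_NAMES, collapse = ", ")), call. = FALSE)
    }
    v <- over[[nm]]
    stopifnot(length(v) == 2)
    r[nm, ] <- as.numeric(v)
  }
  if (any(r$lower >= r$upper)) {
    stop("every trait must satisfy lower < upper", call. = FALSE)
  }
  r
}

#' Flowering-window stress parameter sets
#'
#' Parameters controlling heat and drought damage to grain number around
#' flowering: `HSGNT` (deg C) the daily-maximum temperature threshold above
#' which grain number is reduced, `HSGNR` (fraction per deg C per day) the
#' reduction rate, `DSGNT` the water-stress-index threshold below which
#' drought reduces grain number, `DSGNS` (fraction per unit stress per day)
#' the drought sensitivity, and `DSGNRMax` the cap on the total
#' drought-induced reduction. The `"iS"` (sensitive) set damages grain
#' number readily; the `"iT"` (tolerant) set requires hotter, drier spells
#' and caps the damage lower. Values are package defaults standing in for a
#' cultivar calibration, not measurements.
#'
#' @param mode `"iS"` or `"iT"`.
#' @return Named numeric vector of the five parameters.
#' @export
stress_params <- function(mode = c("iS", "iT")) {
  mode <- match.arg(mode)
  if (mode == "iS") {
    c(HSGNT = 27, HSGNR = 0.05, DSGNT = 0.6, DSGNS = 0.3, DSGNRMax = 0.9)
  } else {
    c(HSGNT = 32, HSGNR = 0.01, DSGNT = 0.4, DSGNS = 0.1, DSGNRMax = 0.3)
  }
}

#' Construct a cultivar parameter set
#'
#' A cultivar is described by the seven optimizable traits (see
#' [TRAIT_NAMES]), the five flowering-window stress parameters (see
#' [stress_params()]), and fixed physiology: `rue` radiation use efficiency
#' (g dry matter per MJ intercepted PAR), `k_ext` canopy extinction
#' coefficient, `t_base` base temperature (deg C), `grains_per_g` potential
#' grains per g of anthesis biomass, `max_grain_wt` potential single-grain
#' mass (mg), `labile_frac` fraction of anthesis biomass relocatable to
#' grain, and `lue_multiplier` (1.0 for current cultivars; ideotypes use
#' 1.10, representing assimilation gains from an optimal Rubisco
#' specificity at current CO2).
#'
#' @param traits Named numeric vector of the seven traits.
#' @param stress Named numeric vector of the five stress parameters.
#' @param rue,k_ext,t_base,grains_per_g,max_grain_wt,labile_frac,lue_multiplier
#'   Fixed physiology; see Description.
#' @return An object of class `cultivar_params` (a named list).
#' @export
#' @examples
#' cv <- default_cultivar()
#' cv$traits[["P_h"]]
cultivar_params <- function(traits, stress = stress_params("iS"),
                            rue = 2.2, k_ext = 0.5, t_base = 0,
                            grains_per_g = 22, max_grain_wt = 45,
                            labile_frac = 0.25, lue_multiplier = 1.0) {
  traits <- unlist(traits)[TRAIT_NAMES]
  stress <- unlist(stress)[STRESS_NAMES]
  if (anyNA(traits)) {
    stop(sprintf("traits must supply all of: %s",
                 paste(TRAIT_NAMES, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(stress)) {
    stop(sprintf("stress must supply all of: %s",
                 paste(STRESS_NAMES, collapse = ", ")), call. = FALSE)
  }
  if (traits[["W_ss"]] < 1) stop("W_ss must be >= 1", call. = FALSE)
  if (traits[["R_u"]] <= 0 || traits[["R_u"]] > 1) {
    stop("R_u must lie in (0, 1]", call. = FALSE)
  }
  if (traits[["P_p"]] < 0 || traits[["P_p"]] > 1) {
    stop("P_p must lie in [0, 1]", call. = FALSE)
  }
  if (!isTRUE(all.equal(lue_multiplier, 1.0)) &&
      !isTRUE(all.equal(lue_multiplier, 1.10))) {
    stop("lue_multiplier must be 1.0 (cultivar) or 1.10 (ideotype)",
         call. = FALSE)
  }
  if (labile_frac < 0 || labile_frac > 1) {
    stop("labile_frac must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(traits = traits, stress = stress,
         rue = rue, k_ext = k_ext, t_base = t_base,
         grains_per_g = grains_per_g, max_grain_wt = max_grain_wt,
         labile_frac = labile_frac, lue_multiplier = lue_multiplier),
    class = "cultivar_params")
}

#' Reference cultivar
#'
#' A mid-range winter-wheat parameterization used as the default local
#' cultivar: every trait sits inside [default_trait_ranges()].
#'
#' @param stress_mode `"iS"` or `"iT"` stress set (local cultivars default
#'   to sensitive).
#' @param ... Passed to [cultivar_params()] (e.g. `lue_multiplier`).
#' @return A `cultivar_params` object.
#' @export
default_cultivar <- function(stress_mode = "iS", ...) {
  cultivar_params(
    traits = c(A_max = 4.5, S_G = 1.0, P_h = 100, P_p = 0.5, G_f = 600,
               R_u = 0.06, W_ss = 2.5),
    stress = stress_params(stress_mode), ...)
}

#' @export
print.cultivar_params <- function(x, ...) {
  cat("<cultivar_params>\n  traits: ",
      paste(sprintf("%s=%.3g", TRAIT_NAMES, x$traits), collapse = " "),
      "\n  stress: ",
      paste(sprintf("%s=%.3g", STRESS_NAMES, x$stress), collapse = " "),
      sprintf("\n  rue=%.2f x%.2f  k_ext=%.2f  t_base=%.1f\n",
              x$rue, x$lue_multiplier, x$k_ext, x$t_base))
  invisible(x)
}

# Replace the optimizable traits of a cultivar (used by the optimizer).
set_traits <- function(cv, traits) {
  cv$traits[TRAIT_NAMES] <- traits[TRAIT_NAMES]
  cv
}

#' Soil profile
#'
#' A single-bucket soil water store. The default 177 mm available water
#' capacity describes a common medium profile used to keep soil effects
#' identical across sites.
#'
#' @param awc Total available water capacity, mm (> 0).
#' @param initial_fill Fraction of `awc` present at sowing, in `[0, 1]`.
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(awc = 177, initial_fill = 0.9) {
  if (awc <= 0) stop("awc must be > 0", call. = FALSE)
  if (initial_fill < 0 || initial_fill > 1) {
    stop("initial_fill must lie in [0, 1]", call. = FALSE)
  }
  structure(list(awc = awc, initial_fill = initial_fill),
            class = "soil_profile")
}

#' Crop management description
#'
#' Rainfed, optimally managed conditions: no irrigation, no nutrient
#' limitation, no biotic losses. CO2 is held at the single level 364 ppm
#' used throughout the analysis (no response function is applied; the
#' assimilation gain of an optimal Rubisco specificity enters through the
#' ideotype `lue_multiplier` instead).
#'
#' @param sowing_doy Day of year of sowing.
#' @param latitude Site latitude in degrees north (drives day length).
#' @param co2_ppm Atmospheric CO2; fixed at 364 in this analysis.
#' @param water_regime Only `"rainfed"` is supported.
#' @param nutrients Only `"non-limiting"` is supported.
#' @return An object of class `management`.
#' @export
management <- function(sowing_doy = 289, latitude = 50, co2_ppm = 364,
                       water_regime = "rainfed",
                       nutrients = "non-limiting") {
  if (!identical(as.numeric(co2_ppm), 364)) {
    stop("co2_ppm is fixed at 364 ppm in this analysis", call. = FALSE)
  }
  water_regime <- match.arg(water_regime, "rainfed")
  nutrients <- match.arg(nutrients, "non-limiting")
  sowing_doy <- as.integer(sowing_doy)
  if (sowing_doy < 1L || sowing_doy > 365L) {
    stop("sowing_doy must be in [1, 365]", call. = FALSE)
  }
  if (abs(latitude) > 67) stop("latitude must lie in [-67, 67]", call. = FALSE)
  structure(list(sowing_doy = sowing_doy, latitude = as.numeric(latitude),
                 co2_ppm = 364, water_regime = water_regime,
                 nutrients = nutrients),
            class = "management")
}

#' Management matched to a site
#'
#' Convenience constructor taking sowing date and latitude from a
#' [site_climate()] object.
#'
#' @param site A `site_climate`.
#' @param ... Passed to [management()].
#' @return A `management` object.
#' @export
management_for_site <- function(site, ...) {
  stopifnot(inherits(site, "site_climate"))
  management(sowing_doy = site$sowing_doy, latitude = site$latitude, ...)
}
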