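# Shared builders and independent oracles for the test suite.

# A weather slice with every day identical (constant forcing).
constant_weather <- function(days = 500, tmin = 8, tmax = 18, precip = 5,
                             rad = 15, doy_start = 289) {
  data.frame(day = seq_len(days),
             doy = ((doy_start - 1 + seq_len(days) - 1) %% 365) + 1,
             tmin = tmin, tmax = tmax, precip = precip, rad = rad)
}

# Independent spreadsheet-style re-computation of the season recurrence
# under arbitrary forcing, written directly from the documented model
# equations (not from the package source). Returns yield and biomass in
# t/ha plus the grain number.
oracle_season <- function(cv, w, awc = 177, initial_fill = 0.9, lat = 50) {
  n_leaf <- 9; booting <- 2; d_base <- 8; d_sat <- 15; f_min <- 0.25
  sen_base <- 350; tpi <- 0.45; par_frac <- 0.5; halfwidth <- 4
  tr <- cv$traits; st <- cv$stress
  days <- nrow(w)

  # own day-length geometry (same declination convention, separate code)
  dlen <- function(doy) {
    dec <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
    x <- -tan(lat * pi / 180) * tan(dec)
    24 / pi * acos(pmin(1, pmax(-1, x)))
  }

  stored <- initial_fill * awc
  biomass <- 0; cum <- 0; post <- 0; sen <- 0
  anth_d <- NA; anth_b <- NA; mat_d <- days
  stress_hist <- numeric(days)
  tt_anth <- (n_leaf + booting) * tr[["P_h"]]
  sen_dur <- sen_base * (1 + tr[["S_G"]])
  flowering <- FALSE
  for (d in seq_len(days)) {
    if (!flowering) {
      lai <- tr[["A_max"]] * min(1, cum / (n_leaf * tr[["P_h"]]))
    } else {
      lai <- tr[["A_max"]] * max(0, 1 - sen / sen_dur)
    }
    ipar <- par_frac * w$rad[d] * (1 - exp(-cv$k_ext * lai))
    demand <- tpi * ipar
    avail <- stored + w$precip[d]
    drain <- max(0, avail - awc)
    avail <- avail - drain
    transp <- min(demand, tr[["R_u"]] * avail)
    stored <- avail - transp
    si <- if (demand > 0) transp / demand else 1
    stress_hist[d] <- si
    biomass <- biomass + cv$rue * cv$lue_multiplier * ipar * si
    tt <- max(0, (w$tmin[d] + w$tmax[d]) / 2 - cv$t_base)
    if (!flowering) {
      pf <- 1 - tr[["P_p"]] * max(0, d_sat - dlen(w$doy[d])) / (d_sat - d_base)
      pf <- min(1, max(f_min, pf))
      cum <- cum + tt * pf
      if (cum >= tt_anth) {
        flowering <- TRUE; anth_d <- d; anth_b <- biomass
      }
    } else {
      post <- post + tt
      sen <- sen + tt * (1 + (tr[["W_ss"]] - 1) * (1 - si))
      if (post >= tr[["G_f"]] || sen >= sen_dur) { mat_d <- d; break }
    }
  }
  if (is.na(anth_d)) return(list(yield = 0, biomass = biomass / 100,
                                 grain_number = 0))
  win <- max(1, anth_d - halfwidth):min(mat_d, anth_d + halfwidth)
  heat <- min(1, sum(st[["HSGNR"]] * pmax(0, w$tmax[win] - st[["HSGNT"]])))
  drought <- min(st[["DSGNRMax"]],
                 sum(st[["DSGNS"]] * pmax(0, st[["DSGNT"]] - stress_hist[win])))
  gn <- cv$grains_per_g * anth_b * (1 - heat) * (1 - drought)
  supply <- (biomass - anth_b) +
    cv$labile_frac * anth_b * min(1, post / tr[["G_f"]])
  yield <- min(supply, gn * cv$max_grain_wt / 1000)
  list(yield = yield / 100, biomass = biomass / 100, grain_number = gn,
       anthesis = anth_d, maturity = mat_d)
}

# One reduced-scale optimization (10 weather years, 3 starts, generation
# cap 50) shared by several tests; computed lazily and cached.
.reduced_cache <- new.env(parent = emptyenv())
reduced_optimization <- function() {
  if (is.null(.reduced_cache$opt)) {
    site <- site_preset("temperate_CW")
    w <- generate_weather(site, years = 10, seed = split_seed(42, "accept"))
    mgmt <- management_for_site(site)
    .reduced_cache$site <- site
    .reduced_cache$series <- w
    .reduced_cache$mgmt <- mgmt
    .reduced_cache$opt <- optimize_ideotype(
      w, soil_profile(), mgmt, default_cultivar(), stress_mode = "iS",
      seed = 42, n_starts = 3, patience = 20, max_gen = 50)
  }
  .reduced_cache
}
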