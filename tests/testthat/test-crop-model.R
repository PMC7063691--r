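# Process operations and the daily season simulator.

test_that("thermal time is the base-floored daily mean", {
  expect_equal(daily_thermal_time(5, 15, 0), 10)
  expect_equal(daily_thermal_time(-10, -2, 0), 0)
  expect_equal(daily_thermal_time(-2, 10, 0), 4)
  expect_error(daily_thermal_time(10, 5), "tmax")
})

test_that("photoperiod factor ramps between base and saturating day length", {
  expect_equal(photoperiod_factor(16, 0.9), 1)   # above saturation
  expect_equal(photoperiod_factor(10, 0), 1)     # insensitive cultivar
  expect_equal(photoperiod_factor(10, 0.7), 0.5) # 1 - 0.7 * 5/7
  expect_equal(photoperiod_factor(2, 1), 0.25)   # clamped at the floor
  expect_error(photoperiod_factor(10, 1.5), "P_p")
})

test_that("soil bucket conserves water and limits uptake by roots", {
  s <- soil_water_step(100, 0, 0, 0.1, 177)
  expect_equal(s$stored, 100)
  expect_equal(s$stress_index, 1)
  s <- soil_water_step(50, 0, 10, 0.1, 177)
  expect_equal(s$actual_transp, 5)
  expect_equal(s$stress_index, 0.5)
  s <- soil_water_step(170, 20, 0, 0.1, 177)
  expect_equal(s$drainage, 13)
  expect_error(soil_water_step(-1, 0, 0, 0.1, 177), "non-negative")
  # exact mass balance over random inputs
  set.seed(101)
  for (i in 1:200) {
    stored <- runif(1, 0, 177); precip <- rexp(1, 1 / 5)
    pot <- runif(1, 0, 8); ru <- runif(1, 0.02, 0.12)
    s <- soil_water_step(stored, precip, pot, ru, 177)
    expect_equal(stored + precip,
                 s$stored + s$actual_transp + s$drainage,
                 tolerance = 1e-12)
    expect_true(s$stress_index >= 0 && s$stress_index <= 1)
  }
})

test_that("flowering-window damage functions follow their linear forms", {
  expect_equal(heat_stress_gn_reduction(c(20, 25, 26.9), 27, 0.05), 0)
  expect_equal(heat_stress_gn_reduction(c(25, 32), 27, 0.04), 0.2)
  expect_equal(heat_stress_gn_reduction(rep(40, 10), 27, 0.05), 1)
  expect_error(heat_stress_gn_reduction(numeric(0), 27, 0.05), "window")

  expect_equal(drought_stress_gn_reduction(c(0.7, 1), 0.6, 0.3, 0.9), 0)
  expect_equal(drought_stress_gn_reduction(c(0.1, 1), 0.6, 0.3, 0.9), 0.15)
  expect_equal(drought_stress_gn_reduction(rep(0, 20), 0.6, 0.3, 0.9), 0.9)
  expect_error(drought_stress_gn_reduction(numeric(0), 0.6, 0.3, 0.9),
               "window")
  expect_error(drought_stress_gn_reduction(c(0.5, 1.2), 0.6, 0.3, 0.9),
               "stress")
})

test_that("senescence acceleration interpolates linearly in stress", {
  expect_equal(senescence_multiplier(1, 3), 1)
  expect_equal(senescence_multiplier(0, 3), 3)
  expect_equal(senescence_multiplier(0.5, 2), 1.5)
  expect_error(senescence_multiplier(0.5, 0.5), "W_ss")
})

test_that("a zero-radiation season yields nothing", {
  w <- constant_weather(500, rad = 0)
  r <- simulate_season(default_cultivar(), w, soil_profile(), management())
  expect_equal(r$yield, 0)
  expect_equal(r$biomass, 0)
  expect_equal(r$cum_ipar, 0)
})

test_that("the simulator matches the independent recurrence oracle", {
  # constant forcing, several cultivars including photoperiod-sensitive
  # and water-stressed configurations
  cases <- list(
    list(cv = default_cultivar(), w = constant_weather(500)),
    list(cv = cultivar_params(
      traits = c(A_max = 7, S_G = 0.2, P_h = 80, P_p = 0, G_f = 800,
                 R_u = 0.03, W_ss = 3.5)),
      w = constant_weather(500, precip = 1.2, rad = 18)),  # droughty
    list(cv = cultivar_params(
      traits = c(A_max = 3, S_G = 2, P_h = 130, P_p = 0.8, G_f = 450,
                 R_u = 0.12, W_ss = 1), lue_multiplier = 1.10),
      w = constant_weather(600, tmin = 4, tmax = 12, precip = 3, rad = 9)))
  for (cs in cases) {
    got <- simulate_season(cs$cv, cs$w, soil_profile(), management())
    want <- oracle_season(cs$cv, cs$w)
    expect_equal(got$yield, want$yield, tolerance = 1e-7)
    expect_equal(got$biomass, want$biomass, tolerance = 1e-7)
    expect_equal(got$grain_number, want$grain_number, tolerance = 1e-7)
    expect_equal(got$anthesis_das, want$anthesis)
    expect_equal(got$maturity_das, want$maturity)
  }
})

test_that("oracle agreement extends to stochastic weather", {
  site <- site_preset("continental_CE")
  w <- generate_weather(site, 2, seed = 21)
  slice <- as.data.frame(w[site$sowing_doy + 0:420, ])
  mgmt <- management_for_site(site)
  got <- simulate_season(default_cultivar(), slice, soil_profile(), mgmt)
  want <- oracle_season(default_cultivar(), slice, lat = site$latitude)
  expect_equal(got$yield, want$yield, tolerance = 1e-7)
  expect_equal(got$biomass, want$biomass, tolerance = 1e-7)
})

test_that("one hot flowering day cuts grain number by the closed form", {
  st <- stress_params("iS")
  # warm, well-watered, sink-limited season (few grains per g)
  cv <- cultivar_params(
    traits = c(A_max = 5, S_G = 1, P_h = 90, P_p = 0, G_f = 700,
               R_u = 0.1, W_ss = 1.5),
    grains_per_g = 8)
  w <- constant_weather(500, tmin = 10, tmax = 20, precip = 8, rad = 16)
  base <- simulate_season(cv, w, soil_profile(), management())
  w_hot <- w
  hot_day <- base$anthesis_das + 2   # inside the +/- 4 day window
  w_hot$tmax[hot_day] <- st[["HSGNT"]] + 5
  hot <- simulate_season(cv, w_hot, soil_profile(), management())
  expect_lt(hot$yield, base$yield)
  expect_equal(hot$grain_number / base$grain_number,
               1 - st[["HSGNR"]] * 5, tolerance = 1e-9)
})

test_that("raising the heat threshold never decreases yield", {
  site <- site_preset("hot_dry_SW")
  w <- generate_weather(site, 6, seed = 5)
  mgmt <- management_for_site(site)
  lo <- default_cultivar(); lo$stress[["HSGNT"]] <- 24
  hi <- default_cultivar(); hi$stress[["HSGNT"]] <- 30
  y_lo <- simulate_multi_year(lo, w, soil_profile(), mgmt)
  y_hi <- simulate_multi_year(hi, w, soil_profile(), mgmt)
  per_lo <- vapply(y_lo$per_year, `[[`, numeric(1), "yield")
  per_hi <- vapply(y_hi$per_year, `[[`, numeric(1), "yield")
  expect_true(all(per_hi >= per_lo))
})

test_that("faster stress senescence does not raise mean yield", {
  site <- site_preset("hot_dry_SW")
  w <- generate_weather(site, 6, seed = 6)
  mgmt <- management_for_site(site)
  lo <- default_cultivar(); lo$traits[["W_ss"]] <- 1.2
  hi <- default_cultivar(); hi$traits[["W_ss"]] <- 3.8
  y_lo <- simulate_multi_year(lo, w, soil_profile(), mgmt)
  y_hi <- simulate_multi_year(hi, w, soil_profile(), mgmt)
  expect_lte(y_hi$mean_yield, y_lo$mean_yield)
})

test_that("the ideotype LUE multiplier scales unstressed biomass by 10%", {
  w <- constant_weather(500, precip = 20)  # soil never limiting
  cv1 <- default_cultivar()
  cv2 <- default_cultivar(lue_multiplier = 1.10)
  r1 <- simulate_season(cv1, w, soil_profile(), management())
  r2 <- simulate_season(cv2, w, soil_profile(), management())
  expect_equal(r2$biomass / r1$biomass, 1.10, tolerance = 1e-9)
})

test_that("season results respect physical and phenological invariants", {
  soil <- soil_profile()
  for (p in c("cool_wet_NW", "hot_dry_SW")) {
    site <- site_preset(p)
    w <- generate_weather(site, 8, seed = 13)
    mgmt <- management_for_site(site)
    ys <- simulate_multi_year(default_cultivar(), w, soil, mgmt)
    for (r in ys$per_year) {
      expect_true(r$hi >= 0 && r$hi <= 1)
      expect_lte(r$yield, r$biomass + 1e-12)
      if (r$biomass > 0) {
        expect_true(r$anthesis_das >= 1)
        expect_lt(r$anthesis_das, r$maturity_das)
      }
      wb <- r$water
      expect_equal(wb$initial + wb$precip,
                   wb$final + wb$transp + wb$drainage,
                   tolerance = 1e-6)
    }
  }
})

test_that("yield statistics use the population-SD CV convention", {
  st <- yield_stats(c(8, 10, 12), c(0.5, 0.52, 0.48))
  expect_equal(st$mean_yield, 10)
  expect_equal(st$cv, 20)          # population sd 2 over mean 10
  expect_equal(st$mean_hi, 0.5)
  expect_error(yield_stats(5, 0.5), "2 years")
})

test_that("constant weather across years gives zero yield CV", {
  w <- do.call(rbind, replicate(3, constant_weather(365), simplify = FALSE))
  w$day <- seq_len(nrow(w))
  w$doy <- rep(1:365, 3)
  ys <- simulate_multi_year(default_cultivar(), w, soil_profile(),
                            management(sowing_doy = 289))
  expect_equal(ys$cv, 0, tolerance = 1e-10)
  expect_equal(ys$n_years, 3)
})

test_that("multi-year simulation is deterministic and validates input", {
  site <- site_preset("temperate_CW")
  w <- generate_weather(site, 4, seed = 9)
  mgmt <- management_for_site(site)
  a <- simulate_multi_year(default_cultivar(), w, soil_profile(), mgmt)
  b <- simulate_multi_year(default_cultivar(), w, soil_profile(), mgmt)
  expect_identical(a, b)
  expect_error(
    simulate_multi_year(default_cultivar(), w[1:365, ], soil_profile(),
                        mgmt),
    "2")
  bad <- constant_weather(500)
  bad$rad[100] <- NA
  expect_error(simulate_season(default_cultivar(), bad, soil_profile(),
                               management()), "finite")
})
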