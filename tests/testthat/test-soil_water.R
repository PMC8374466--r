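test_that("stress coefficients hit their anchors and interpolate linearly", {
  soil <- builtin_soil("clay_loam")
  s <- stress_settings()

  ks <- stress_coefficients(0, soil$theta_fc, soil, s)
  expect_equal(unlist(ks[c("ks_expansion", "ks_stomatal",
                           "ks_senescence", "ks_aeration")]),
               c(ks_expansion = 1, ks_stomatal = 1,
                 ks_senescence = 1, ks_aeration = 1))

  ks <- stress_coefficients(1, soil$theta_pwp, soil, s)
  expect_equal(ks$ks_expansion, 0)
  expect_equal(ks$ks_stomatal, 0)

  # hand linear interpolation: p_upper 0.5, p_lower 1, depletion 0.75 -> 0.5
  s2 <- stress_settings(p_upper_stomatal = 0.5)
  ks <- stress_coefficients(0.75, 0.3, soil, s2)
  expect_equal(ks$ks_stomatal, 0.5)

  # aeration only bites within the anaerobiosis margin below saturation
  ks_wet <- stress_coefficients(0, soil$theta_sat - 0.01, soil, s)
  expect_lt(ks_wet$ks_aeration, 1)
  ks_dryish <- stress_coefficients(0, soil$theta_sat - 0.06, soil, s)
  expect_equal(ks_dryish$ks_aeration, 1)

  expect_error(stress_coefficients(1.2, 0.3, soil, s), "depletion")
})

test_that("single bucket steps close their daily mass balance", {
  soil <- builtin_soil("clay_loam")
  st <- init_soil_water(soil, zr = 0.5)

  # closed system: nothing in, nothing out
  step <- water_balance_step(st, soil, water_in = 0, eto = 0, cc = 0.5,
                             zr_new = st$zr)
  expect_equal(step$state$theta, st$theta)
  expect_equal(unlist(step$fluxes[c("infiltration", "drainage", "es", "tr")]),
               c(infiltration = 0, drainage = 0, es = 0, tr = 0))

  # dry soil: no transpiration supply
  dry <- init_soil_water(soil, zr = 0.5, theta_init = soil$theta_pwp)
  step <- water_balance_step(dry, soil, water_in = 0, eto = 5, cc = 0.5,
                             zr_new = 0.5, tr_demand = 4)
  expect_equal(step$fluxes$tr, 0)
  expect_equal(step$fluxes$tr_potential_supply, 0, tolerance = 1e-9)

  # bucket oracle: at FC, 20 mm in, tau = 1 -> all the excess drains
  free <- soil_profile("clay loam", 0.23, 0.39, 0.50, ksat = 125,
                       drainage_tau = 1)
  st <- init_soil_water(free, zr = 1.0)
  step <- water_balance_step(st, free, water_in = 20, eto = 0, cc = 0,
                             zr_new = 1.0)
  expect_equal(step$fluxes$drainage, 20, tolerance = 1e-6)
  expect_equal(step$state$theta, free$theta_fc, tolerance = 1e-9)
})

test_that("theta stays inside [0, sat] under random forcing sequences", {
  soil <- builtin_soil("clay_loam")
  for (seed in 1:10) {
    set.seed(seed)
    st <- init_soil_water(soil, zr = 0.3, theta_init = runif(1, 0.1, 0.5))
    zr <- 0.3
    for (i in 1:60) {
      zr <- min(2, zr + runif(1, 0, 0.05))
      step <- water_balance_step(st, soil,
                                 water_in = rexp(1, 1 / 8) * rbinom(1, 1, 0.4),
                                 eto = runif(1, 0, 8), cc = runif(1),
                                 zr_new = zr, tr_demand = runif(1, 0, 6))
      st <- step$state
      expect_true(st$theta >= 0 && st$theta <= soil$theta_sat + 1e-12)
      fl <- step$fluxes
      expect_lt(abs(fl$delta_storage - (fl$root_zone_gain + fl$infiltration -
                                          fl$drainage - fl$es - fl$tr)),
                1e-9)
    }
  }
})

test_that("root shrinkage and negative fluxes are rejected", {
  soil <- builtin_soil("clay_loam")
  st <- init_soil_water(soil, zr = 1.0)
  expect_error(water_balance_step(st, soil, 0, 0, 0, zr_new = 0.5), "shrink")
  expect_error(water_balance_step(st, soil, -1, 0, 0, zr_new = 1), "negative")
})

test_that("daily saturating irrigation keeps the three depletion Ks at one", {
  res <- unstressed_grain_run()
  after_emergence <- res$daily$das >= 1
  expect_true(all(res$daily$ks_expansion[after_emergence] == 1))
  expect_true(all(res$daily$ks_stomatal[after_emergence] == 1))
  expect_true(all(res$daily$ks_senescence[after_emergence] == 1))
})

test_that("soil files round-trip and reject incomplete documents", {
  soil <- builtin_soil("clay_loam")
  path <- withr::local_tempfile(fileext = ".soil")
  write_soil(soil, path)
  expect_equal(read_soil(path), soil)
  writeLines(c("texture = sand", "pwp = 0.05", "fc = 0.15"), path)
  expect_error(read_soil(path), "sat")
})
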