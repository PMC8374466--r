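test_that("a grain-hemp season runs day 0 through maturity at day 140", {
  res <- unstressed_grain_run()
  expect_equal(nrow(res$daily), 141)
  last <- res$daily[nrow(res$daily), ]
  expect_equal(last$das, 140)
  expect_equal(as.character(last$stage), "mature")
  expect_equal(res$finals$maturity_date, as.Date("2014-07-31") + 140)
  # finals consistent with the last row
  expect_equal(last$b, res$finals$biomass)
  expect_equal(last$hi, res$finals$harvest_index)
})

test_that("simulations are deterministic for identical inputs", {
  p <- builtin_ideotype("hemp_fibre")
  ws <- default_weather(seed = 9)
  a <- run_simulation(p, ws)
  b <- run_simulation(p, ws)
  expect_identical(a, b)
})

test_that("final biomass satisfies the global WP x sum(Tr/ETo) identity", {
  p <- builtin_ideotype("hemp_grain")
  ws <- default_weather(seed = 3)
  res <- run_simulation(p, ws)
  eto <- ws$eto[match(res$daily$date, ws$date)]
  b_identity <- p$wp_normalized * sum(res$daily$tr / eto) / 100  # t/ha
  expect_lt(abs(res$finals$biomass - b_identity) /
              max(res$finals$biomass, 1e-12), 1e-9)
})

test_that("seasonal water balance closes to well below 1e-4 mm", {
  for (seed in c(3, 42)) {
    res <- run_simulation(builtin_ideotype("hemp_grain"),
                          default_weather(seed = seed))
    expect_lt(res$finals$water_balance_residual_mm, 1e-4)
  }
})

test_that("no water means no biomass and no yield", {
  p <- builtin_ideotype("hemp_grain")
  soil <- builtin_soil("clay_loam")
  dates <- as.Date("2014-07-31") + 0:140
  desert <- weather_series(data.frame(
    date = dates, tmax = 30, tmin = 15, rain = 0, eto = 5))
  mgmt <- management_config(
    initial_soil_water = soil$theta_pwp / soil$theta_fc)  # start at PWP
  res <- run_simulation(p, desert, soil, mgmt)
  expect_equal(res$finals$biomass, 0)
  expect_equal(res$finals$yield, 0)
})

test_that("scaling rainfall up never lowers final biomass (20 seeds)", {
  p <- builtin_ideotype("hemp_grain")
  for (seed in 1:20) {
    ws <- default_weather(seed = seed)
    dry <- ws; dry$rain <- 0.4 * dry$rain
    b_dry <- run_simulation(p, dry)$finals$biomass
    b_wet <- run_simulation(p, ws)$finals$biomass
    expect_lte(b_dry, b_wet + 1e-9)
  }
})

test_that("insufficient weather coverage is a clear error", {
  p <- builtin_ideotype("hemp_grain")
  short <- default_weather(seed = 1, n_days = 100)
  expect_error(run_simulation(p, short), "weather does not cover")
})

test_that("swapping grain for fibre changes yield through hi and wp as production predicts", {
  ws <- default_weather(seed = 12)
  grain <- builtin_ideotype("hemp_grain")
  fibre <- builtin_ideotype("hemp_fibre")
  rg <- run_simulation(grain, ws)
  rf <- run_simulation(fibre, ws)
  # each run independently satisfies yield = biomass x hi
  expect_equal(rg$finals$yield,
               yield_final(rg$finals$biomass, rg$finals$harvest_index))
  expect_equal(rf$finals$yield,
               yield_final(rf$finals$biomass, rf$finals$harvest_index))
  # and biomass = wp x cumulative normalized transpiration
  expect_equal(rg$finals$biomass, grain$wp_normalized * rg$finals$tr_cum_norm / 100)
  expect_equal(rf$finals$biomass, fibre$wp_normalized * rf$finals$tr_cum_norm / 100)
  # fibre harvests the whole biomass, grain less than a quarter of it
  expect_equal(rf$finals$yield, rf$finals$biomass)
  expect_lt(rg$finals$yield / rg$finals$biomass, 0.3)
})

test_that("irrigation is credited on its scheduled dates", {
  p <- builtin_ideotype("hemp_grain")
  soil <- builtin_soil("clay_loam")
  dates <- as.Date("2014-07-31") + 0:140
  dryw <- weather_series(data.frame(
    date = dates, tmax = 28, tmin = 16, rain = 0, eto = 4))
  irr <- data.frame(date = as.Date("2014-08-10"), mm = 25)
  res <- run_simulation(p, dryw, soil,
                        management_config(irrigation_schedule = irr))
  row <- res$daily[res$daily$date == as.Date("2014-08-10"), ]
  expect_equal(row$infiltration, 25, tolerance = 1e-9)
})
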