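# Calibration runs are the slow part of the suite; these tests use single
# steps and one weather seed, leaving the multi-seed recovery experiment to
# the acceptance suite.

test_that("a base set that already explains the observations is left untouched", {
  p <- builtin_ideotype("hemp_grain")
  truth <- make_truth_observations(p, weather_seed = 7)
  fit <- calibrate_sequential(p, truth$obs, truth$weather,
                              steps = list(calibration_step(
                                "canopy_rate", list(cgc = c(0.05, 0.40)))))
  expect_equal(fit$params, p)
  expect_equal(fit$objective, 0)
  expect_false(any(fit$trace$accepted))
})

test_that("a perturbed canopy growth rate is recovered from synthetic observations", {
  truth <- builtin_ideotype("hemp_grain")
  truth$cgc <- 0.20
  made <- make_truth_observations(truth, weather_seed = 7)
  base <- builtin_ideotype("hemp_grain")  # starts at cgc = 0.24917
  fit <- calibrate_sequential(base, made$obs, made$weather,
                              steps = list(calibration_step(
                                "canopy_rate", list(cgc = c(0.05, 0.40)))))
  expect_lt(abs(fit$params$cgc - 0.20) / 0.20, 0.10)
  expect_lte(fit$objective, min(fit$trace$objective))
})

test_that("objective never increases across accepted moves and steps", {
  truth <- builtin_ideotype("hemp_grain")
  truth$hi_ref <- 0.30
  made <- make_truth_observations(truth, weather_seed = 11)
  base <- builtin_ideotype("hemp_grain")
  steps <- list(
    calibration_step("canopy_rate", list(cgc = c(0.05, 0.40))),
    calibration_step("canopy_max_and_hi",
                     list(ccx = c(0.5, 0.99), hi_ref = c(0.05, 1.0))))
  fit <- calibrate_sequential(base, made$obs, made$weather, steps = steps)
  acc <- fit$trace[fit$trace$accepted, ]
  expect_true(all(diff(acc$objective) <= 1e-12))
  init_obj <- fit$trace$objective[1]  # first candidate may or may not improve
  expect_lte(fit$objective, init_obj + 1e-12)
  expect_lt(abs(fit$params$hi_ref - 0.30) / 0.30, 0.05)
})

test_that("recalibrating from the calibrated result changes nothing", {
  truth <- builtin_ideotype("hemp_grain")
  truth$cgc <- 0.18
  made <- make_truth_observations(truth, weather_seed = 5)
  steps <- list(calibration_step("canopy_rate", list(cgc = c(0.05, 0.40))))
  fit1 <- calibrate_sequential(builtin_ideotype("hemp_grain"),
                               made$obs, made$weather, steps = steps)
  fit2 <- calibrate_sequential(fit1$params, made$obs, made$weather,
                               steps = steps)
  expect_equal(fit2$params, fit1$params)
})

test_that("misconfigured steps and empty observations are rejected", {
  p <- builtin_ideotype("hemp_grain")
  made <- make_truth_observations(p, weather_seed = 2)
  expect_error(
    calibrate_sequential(p, made$obs, made$weather,
                         steps = list(calibration_step("bad",
                                                       list(xyz = c(0, 1))))),
    "unknown parameter")
  empty <- made$obs[0, ]
  expect_error(calibrate_sequential(p, empty, made$weather), "empty")
  expect_error(calibration_step("bad", list(cgc = c(0.4, 0.1))), "bounds")
})

test_that("the shipped default steps encode the sequential order", {
  steps <- default_calibration_steps()
  expect_equal(names(steps),
               c("life_cycle", "canopy_rate", "canopy_max_and_hi",
                 "hi_buildup"))
  expect_setequal(names(steps$life_cycle$params),
                  c("d_emergence", "d_flowering", "d_flowering_length",
                    "d_max_root", "d_senescence", "d_maturity"))
  expect_equal(names(steps$canopy_rate$params), "cgc")
  expect_setequal(names(steps$canopy_max_and_hi$params), c("ccx", "hi_ref"))
  expect_setequal(names(steps$hi_buildup$params),
                  c("d_hi_buildup", "hi_onset_offset"))
})
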