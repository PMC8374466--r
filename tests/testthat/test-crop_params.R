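test_that("built-in ideotypes carry the published parameter values", {
  grain <- builtin_ideotype("hemp_grain")
  expect_equal(grain$wp_normalized, 25)
  expect_equal(grain$cgc, 0.24917)
  expect_equal(grain$hi_ref, 0.23)
  expect_equal(grain$d_maturity, 140L)
  expect_equal(grain$d_flowering, 74L)
  expect_equal(grain$ccx, 0.90)
  expect_equal(grain$zr_max, 2.00)
  expect_equal(grain$stress_settings$p_upper_flowering, 0.90)

  fibre <- builtin_ideotype("hemp_fibre")
  expect_equal(fibre$ccx, 0.95)
  expect_equal(fibre$wp_normalized, 18)
  expect_equal(fibre$hi_ref, 1.00)
  expect_equal(fibre$cdc, 0.09615)
  expect_equal(fibre$d_flowering, 72L)
  expect_true(is.na(fibre$stress_settings$p_upper_flowering))

  base <- builtin_ideotype("sugarcane_baseline")
  expect_equal(base$t_base, 9.0)
  expect_equal(base$cgc, 0.12548)
  expect_equal(base$d_maturity, 365L)
  expect_equal(base$hi_ref, 0.35)
})

test_that("percent-valued quantities are stored as fractions and cc0 derives from density", {
  for (nm in c("hemp_grain", "hemp_fibre", "sugarcane_baseline")) {
    p <- builtin_ideotype(nm)
    expect_true(p$ccx > 0 && p$ccx <= 1)
    expect_true(p$hi_ref > 0 && p$hi_ref <= 1)
  }
  # 140 000 plants/ha x 5 cm^2/plant
  expect_equal(builtin_ideotype("hemp_grain")$cc0, 0.007)
})

test_that("unknown ideotype names raise a distinct error listing valid names", {
  expect_error(builtin_ideotype("maize"), "unknown ideotype")
  expect_error(builtin_ideotype("maize"), "hemp_grain")
})

test_that("all built-ins pass validation with an empty violation list", {
  for (nm in c("hemp_grain", "hemp_fibre", "sugarcane_baseline")) {
    expect_length(validate_parameters(builtin_ideotype(nm)), 0)
  }
})

test_that("validate_parameters names every violated rule", {
  p <- builtin_ideotype("hemp_grain")
  p$zr_min <- 3.0; p$zr_max <- 2.0
  expect_match(validate_parameters(p), "zr_min <= zr_max", all = FALSE)

  q <- builtin_ideotype("hemp_grain")
  q$t_base <- 45; q$t_upper <- 40
  expect_match(validate_parameters(q), "t_base < t_upper", all = FALSE)

  r <- builtin_ideotype("hemp_grain")
  r$cc0 <- 0.95; r$ccx <- 0.90
  expect_match(validate_parameters(r), "cc0 < ccx violated", all = FALSE)

  # several simultaneous violations are all reported, not just the first
  s <- builtin_ideotype("hemp_grain")
  s$cc0 <- 0.95; s$ccx <- 0.90; s$t_base <- 45; s$t_upper <- 40
  expect_gte(length(validate_parameters(s)), 2)
})

test_that("crop files round-trip losslessly through writer and reader", {
  for (nm in c("hemp_grain", "hemp_fibre", "sugarcane_baseline")) {
    p <- builtin_ideotype(nm)
    path <- withr::local_tempfile(fileext = ".crop")
    write_crop_parameters(p, path)
    q <- load_crop_parameters(path)
    expect_equal(q, p)
  }
})

test_that("loading rejects missing keys and invalid parameter documents", {
  p <- builtin_ideotype("hemp_grain")
  path <- withr::local_tempfile(fileext = ".crop")
  write_crop_parameters(p, path)

  lines <- readLines(path)
  writeLines(lines[!grepl("^wp_normalized_g_m2", lines)], path)
  expect_error(load_crop_parameters(path), "wp_normalized_g_m2")

  write_crop_parameters(p, path)
  lines <- readLines(path)
  lines <- sub("^ccx_frac = .*", "ccx_frac = 0.90", lines)
  lines <- c(lines, "")  # cc0 is derived; force it above ccx via density
  lines <- sub("^plant_population_per_ha = .*",
               "plant_population_per_ha = 20000000", lines)
  writeLines(lines, path)
  expect_error(load_crop_parameters(path), "cc0 < ccx violated")
})

test_that("packaged crop and soil fixtures match the built-ins", {
  dir <- system.file("extdata", package = "ideocrop")
  expect_equal(load_crop_parameters(file.path(dir, "hemp_grain.crop")),
               builtin_ideotype("hemp_grain"))
  expect_equal(load_crop_parameters(file.path(dir, "hemp_fibre.crop")),
               builtin_ideotype("hemp_fibre"))
  expect_equal(read_soil(file.path(dir, "clay_loam.soil")),
               builtin_soil("clay_loam"))
})
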