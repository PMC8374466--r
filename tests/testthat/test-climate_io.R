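test_that("CSV weather round-trips and structural errors are specific", {
  ws <- default_weather(seed = 5, n_days = 90)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather(ws, path)
  back <- read_weather(path, dialect = "csv")
  expect_equal(as.data.frame(back), as.data.frame(ws), tolerance = 1e-12)

  df <- as.data.frame(ws)
  gap <- df[-10, ]
  write.csv(gap, path, row.names = FALSE)
  expect_error(read_weather(path, "csv"), "non-contiguous")
  expect_error(read_weather(path, "csv"), as.character(df$date[9]))

  bad <- as.data.frame(ws)
  bad$tmax[3] <- bad$tmin[3] - 1
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_weather(path, "csv"), "tmax < tmin at row 3")
})

test_that("aquacrop split files merge when aligned and error when not", {
  ws <- default_weather(seed = 7, n_days = 365)
  tmp <- withr::local_tempfile(fileext = ".TMP")
  plu <- withr::local_tempfile(fileext = ".PLU")
  eto <- withr::local_tempfile(fileext = ".ETo")
  header <- c("station: synthetic", "units: mm and degC", "")
  writeLines(c(header, sprintf("%.2f  %.2f", ws$tmax, ws$tmin)), tmp)
  writeLines(c(header, sprintf("%.2f", ws$rain)), plu)
  writeLines(c(header, sprintf("%.2f", ws$eto)), eto)

  merged <- read_weather(c(tmp, plu, eto), "aquacrop_split",
                         start_date = ws$date[1])
  expect_equal(nrow(merged), 365)
  expect_equal(merged$date, ws$date)
  expect_equal(merged$rain, round(ws$rain, 2))

  writeLines(c(header, sprintf("%.2f", ws$rain[1:200])), plu)
  expect_error(read_weather(c(tmp, plu, eto), "aquacrop_split",
                            start_date = ws$date[1]),
               "alignment")
})

test_that("downscaling preserves period means and totals (brute-force oracle)", {
  # constant case
  daily <- downscale_to_daily(rep(20, 12), "monthly", "temperature_mean")
  expect_equal(daily, rep(20, 365), tolerance = 1e-9)

  # single rain period conserves the total exactly
  rain <- downscale_to_daily(60, "monthly", "rain_total",
                             start = as.Date("2014-09-01"), seed = 3)
  expect_length(rain, 30)
  expect_equal(sum(rain), 60, tolerance = 1e-9)
  expect_true(all(rain >= 0))

  # two-month temperature means re-aggregate to the inputs
  daily <- downscale_to_daily(c(10, 20), "monthly", "temperature_mean",
                              start = as.Date("2014-01-01"))
  expect_equal(mean(daily[1:31]), 10, tolerance = 1e-9)
  expect_equal(mean(daily[32:59]), 20, tolerance = 1e-9)

  # conservation on random inputs, both kinds and both period types
  set.seed(99)
  for (period in c("monthly", "decade")) {
    m <- runif(6, -5, 25)
    daily <- downscale_to_daily(m, period, "temperature_mean")
    lens <- diff(c(0, cumsum(if (period == "monthly")
      c(31, 28, 31, 30, 31, 30) else c(10, 10, 11, 10, 10, 8))))
    bounds <- c(0, cumsum(lens))
    agg <- vapply(1:6, function(i)
      mean(daily[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
    expect_equal(agg, m, tolerance = 1e-9)

    r <- runif(6, 0, 120)
    rd <- downscale_to_daily(r, period, "rain_total", seed = 11)
    aggr <- vapply(1:6, function(i)
      sum(rd[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
    expect_equal(aggr, r, tolerance = 1e-9)
  }

  expect_error(downscale_to_daily(c(10, -5), "monthly", "rain_total"),
               "negative rain")
})

test_that("synthetic weather is seeded, valid and centred on its configuration", {
  a <- generate_synthetic_weather(n_days = 200, seed = 42)
  b <- generate_synthetic_weather(n_days = 200, seed = 42)
  expect_identical(a, b)

  dry <- generate_synthetic_weather(default_climate_config(rain_prob = 0),
                                    n_days = 120, seed = 1)
  expect_true(all(dry$rain == 0))

  long <- generate_synthetic_weather(n_days = 3650, seed = 7)
  expect_lt(abs(mean(long$tmax) - 18), 0.5)

  for (seed in 1:15) {
    ws <- generate_synthetic_weather(n_days = 120, seed = seed)
    expect_true(all(ws$tmax >= ws$tmin))
    expect_true(all(ws$rain >= 0) && all(ws$eto >= 0))
  }

  expect_error(
    generate_synthetic_weather(default_climate_config(rain_mean = 0),
                               n_days = 10, seed = 1),
    "rain intensity")
})
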