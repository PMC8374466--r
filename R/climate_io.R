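#' Daily weather series
#'
#' The engine is driven by a contiguous daily series of maximum and minimum
#' air temperature (deg C), rainfall (mm/d) and reference evapotranspiration
#' ETo (mm/d). A weather series is a data.frame with columns
#' `date, tmax, tmin, rain, eto` and class `weather_series`.
#'
#' @param df data.frame with the five canonical columns.
#' @return A validated `weather_series`.
#' @export
weather_series <- function(df) {
  need <- c("date", "tmax", "tmin", "rain", "eto")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("weather series missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  df$date <- as.Date(df$date)
  for (col in c("tmax", "tmin", "rain", "eto")) df[[col]] <- as.numeric(df[[col]])
  .validate_weather(df)
  class(df) <- c("weather_series", "data.frame")
  df
}

.validate_weather <- function(df) {
  if (nrow(df) == 0) stop("empty weather series", call. = FALSE)
  d <- diff(as.integer(df$date))
  if (any(d != 1L)) {
    i <- which(d != 1L)[1]
    stop("non-contiguous series: gap between ", df$date[i], " and ",
         df$date[i + 1L], call. = FALSE)
  }
  bad <- which(df$tmax < df$tmin)
  if (length(bad)) {
    stop("tmax < tmin at row ", bad[1], " (", df$date[bad[1]], ")",
         call. = FALSE)
  }
  if (any(df$rain < 0)) stop("negative rainfall", call. = FALSE)
  if (any(df$eto < 0)) stop("negative ETo", call. = FALSE)
  invisible(df)
}

#' Read a daily weather series
#'
#' Two dialects are supported. `"csv"` expects a single file with header
#' `date,tmax,tmin,rain,eto` (ISO dates, deg C and mm). `"aquacrop_split"`
#' expects the classic three-file layout -- a temperature file (two columns,
#' Tmax Tmin), a rainfall file and an ETo file (one column each) -- as
#' whitespace-delimited numeric tables; header lines are skipped until the
#' first fully numeric row. Split files carry no dates, so `start_date`
#' anchors the series.
#'
#' @param path CSV path, or for the split dialect a character vector of the
#'   three paths (temperature, rain, eto) in that order.
#' @param dialect `"csv"` or `"aquacrop_split"`.
#' @param start_date first day of the series (split dialect only).
#' @return A `weather_series`.
#' @export
read_weather <- function(path, dialect = c("csv", "aquacrop_split"),
                         start_date = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    if (!file.exists(path)) stop("weather file not found: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(weather_series(df))
  }
  if (length(path) != 3L) {
    stop("aquacrop_split dialect needs three paths: temperature, rain, eto",
         call. = FALSE)
  }
  if (is.null(start_date)) {
    stop("aquacrop_split files carry no dates; supply start_date", call. = FALSE)
  }
  tmp <- .read_numeric_table(path[1])
  plu <- .read_numeric_table(path[2])
  eto <- .read_numeric_table(path[3])
  if (ncol(tmp) < 2L) stop("temperature file must have Tmax and Tmin columns",
                           call. = FALSE)
  n <- c(nrow(tmp), nrow(plu), nrow(eto))
  if (length(unique(n)) != 1L) {
    stop("alignment error: split files cover different ranges (",
         paste(n, collapse = ", "), " rows)", call. = FALSE)
  }
  weather_series(data.frame(
    date = as.Date(start_date) + seq_len(n[1]) - 1L,
    tmax = tmp[[1]], tmin = tmp[[2]], rain = plu[[1]], eto = eto[[1]]
  ))
}

# Tolerant numeric-table reader: drop every leading line until the first row
# whose whitespace-separated fields are all numeric.
.read_numeric_table <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  is_num_row <- vapply(strsplit(lines, "\\s+"), function(f) {
    length(f) > 0 && !anyNA(suppressWarnings(as.numeric(f)))
  }, TRUE)
  first <- which(is_num_row)[1]
  if (is.na(first)) stop("no numeric rows in ", path, call. = FALSE)
  rows <- strsplit(lines[first:length(lines)], "\\s+")
  ncols <- length(rows[[1]])
  mat <- do.call(rbind, lapply(rows, function(f) as.numeric(f[seq_len(ncols)])))
  as.data.frame(mat)
}

#' Write a weather series as canonical CSV
#' @param ws a `weather_series`.
#' @param path output path.
#' @export
write_weather <- function(ws, path) {
  utils::write.csv(as.data.frame(ws), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- downscaling -----------------------------------------------------------

.period_lengths <- function(n_periods, period, start) {
  start <- as.Date(start)
  if (period == "monthly") {
    if (as.integer(format(start, "%d")) != 1L) {
      stop("monthly downscaling must start on the first of a month",
           call. = FALSE)
    }
    d <- start
    out <- integer(n_periods)
    for (i in seq_len(n_periods)) {
      nxt <- seq(d, by = "month", length.out = 2L)[2L]
      out[i] <- as.integer(nxt - d)
      d <- nxt
    }
    out
  } else {  # decade: days 1-10, 11-20, 21-end of each month
    dom <- as.integer(format(start, "%d"))
    if (!dom %in% c(1L, 11L, 21L)) {
      stop("decade downscaling must start on day 1, 11 or 21 of a month",
           call. = FALSE)
    }
    d <- start
    out <- integer(n_periods)
    for (i in seq_len(n_periods)) {
      dom <- as.integer(format(d, "%d"))
      if (dom < 21L) {
        len <- 10L
      } else {
        first_next <- seq(as.Date(format(d, "%Y-%m-01")), by = "month",
                          length.out = 2L)[2L]
        len <- as.integer(first_next - d)
      }
      out[i] <- len
      d <- d + len
    }
    out
  }
}

#' Downscale monthly or decade aggregates to a daily series
#'
#' Temperature and ETo aggregates are period means: the daily series is a
#' mean-preserving piecewise-linear interpolation through period-midpoint
#' nodes, i.e. every period's daily mean reproduces the input mean to
#' solver precision, with smooth transitions at period boundaries. Rain
#' aggregates are period totals: each total is placed on seeded
#' pseudo-random wet days within its period (preserving dry spells rather
#' than smearing uniformly) and sums back exactly.
#'
#' @param values numeric vector of per-period aggregates.
#' @param period `"monthly"` or `"decade"` (decades are days 1-10, 11-20,
#'   21-end of month).
#' @param kind `"temperature_mean"`, `"eto_mean"` or `"rain_total"`.
#' @param start first calendar day of the first period.
#' @param seed integer seed for wet-day placement (rain only).
#' @param wet_fraction target fraction of wet days per period (rain only).
#' @return Numeric daily vector; for rain, attribute `scheme` records the
#'   distribution scheme used.
#' @export
downscale_to_daily <- function(values,
                               period = c("monthly", "decade"),
                               kind = c("temperature_mean", "rain_total",
                                        "eto_mean"),
                               start = as.Date("2014-01-01"),
                               seed = 1L, wet_fraction = 0.3) {
  period <- match.arg(period)
  kind <- match.arg(kind)
  if (length(values) < 1L) stop("at least one period required", call. = FALSE)
  lens <- .period_lengths(length(values), period, start)

  if (kind == "rain_total") {
    if (any(values < 0)) stop("negative rain total", call. = FALSE)
    out <- numeric(sum(lens))
    offset <- 0L
    rng <- .with_seed(seed, {
      for (i in seq_along(values)) {
        len <- lens[i]
        if (values[i] > 0) {
          n_wet <- max(1L, round(len * wet_fraction))
          wet <- sample.int(len, n_wet)
          w <- stats::rexp(n_wet)
          out[offset + wet] <- values[i] * w / sum(w)
        }
        offset <- offset + len
      }
      out
    })
    attr(rng, "scheme") <- "seeded-wet-day-placement"
    return(rng)
  }

  # Mean-preserving interpolation: solve for node values at period midpoints
  # so that averaging the interpolated dailies over each period returns the
  # inputs. The map nodes -> period means is linear; build it column by
  # column and invert (n_periods is small).
  n <- length(values)
  mids <- cumsum(lens) - lens / 2 + 0.5  # midpoint in day index units
  days <- seq_len(sum(lens))
  interp <- function(v) {
    stats::approx(x = mids, y = v, xout = days, rule = 2)$y
  }
  if (n == 1L) return(rep(values, lens))
  M <- matrix(0, n, n)
  bounds <- c(0L, cumsum(lens))
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    daily <- interp(e)
    for (i in seq_len(n)) {
      M[i, j] <- mean(daily[(bounds[i] + 1L):bounds[i + 1L]])
    }
  }
  nodes <- solve(M, values)
  interp(nodes)
}

# ---- synthetic weather -----------------------------------------------------

#' Default synthetic-climate configuration
#'
#' Parameters of a temperate, rain-fed daily climate: a seasonal temperature
#' sinusoid with summer peak, stochastic diurnal range, intermittent
#' exponential-intensity rainfall and a smooth seasonal ETo curve. Defaults
#' describe a Po-valley-like temperate site (annual mean Tmax 18 deg C,
#' ~30% wet days) able to drive a 140-day summer season.
#'
#' @param start_date first day of the generated series.
#' @param tmax_mean annual mean of Tmax, deg C.
#' @param tmax_amplitude seasonal half-amplitude of Tmax, deg C.
#' @param peak_doy day-of-year of the warm peak.
#' @param diurnal_range mean Tmax - Tmin, deg C.
#' @param temp_noise_sd day-to-day temperature noise, deg C.
#' @param rain_prob probability any day is wet.
#' @param rain_mean mean wet-day rainfall, mm (exponential).
#' @param eto_mean,eto_amplitude annual mean and seasonal half-amplitude of
#'   ETo, mm/d.
#' @param eto_noise_sd ETo noise, mm/d.
#' @export
default_climate_config <- function(start_date = as.Date("2014-01-01"),
                                   tmax_mean = 18, tmax_amplitude = 11,
                                   peak_doy = 205,
                                   diurnal_range = 9, temp_noise_sd = 2.5,
                                   rain_prob = 0.30, rain_mean = 6,
                                   eto_mean = 2.8, eto_amplitude = 2.2,
                                   eto_noise_sd = 0.3) {
  list(start_date = as.Date(start_date),
       tmax_mean = tmax_mean, tmax_amplitude = tmax_amplitude,
       peak_doy = peak_doy, diurnal_range = diurnal_range,
       temp_noise_sd = temp_noise_sd,
       rain_prob = rain_prob, rain_mean = rain_mean,
       eto_mean = eto_mean, eto_amplitude = eto_amplitude,
       eto_noise_sd = eto_noise_sd)
}

# Run expr with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a seeded synthetic daily weather series
#'
#' Deterministic for a fixed (config, seed). Tmin is always below Tmax
#' (diurnal range truncated at 2 deg C), rainfall and ETo are nonnegative.
#'
#' @param config a [default_climate_config()] list.
#' @param n_days number of days (>= 1).
#' @param seed integer seed.
#' @return A `weather_series`.
#' @examples
#' ws <- generate_synthetic_weather(n_days = 365, seed = 42)
#' @export
generate_synthetic_weather <- function(config = default_climate_config(),
                                       n_days, seed) {
  if (n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  if (config$rain_prob > 0 && config$rain_mean <= 0) {
    stop("non-positive rain intensity", call. = FALSE)
  }
  dates <- config$start_date + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  season <- cos(2 * pi * (doy - config$peak_doy) / 365.25)
  .with_seed(seed, {
    tmax <- config$tmax_mean + config$tmax_amplitude * season +
      stats::rnorm(n_days, 0, config$temp_noise_sd)
    range <- pmax(2, stats::rnorm(n_days, config$diurnal_range, 2))
    tmin <- tmax - range
    wet <- stats::runif(n_days) < config$rain_prob
    rain <- ifelse(wet, stats::rexp(n_days, 1 / config$rain_mean), 0)
    eto <- pmax(0.1, config$eto_mean + config$eto_amplitude * season +
                  stats::rnorm(n_days, 0, config$eto_noise_sd))
    weather_series(data.frame(date = dates, tmax = tmax, tmin = tmin,
                              rain = rain, eto = eto))
  })
}
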