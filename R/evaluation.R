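#' Root mean square error
#'
#' `sqrt(mean((observed - simulated)^2))`, in the variable's own units.
#' For a single observed/simulated pair this is the absolute difference.
#'
#' @param observed,simulated numeric vectors of equal nonzero length.
#' @return RMSE (same units as the inputs).
#' @examples
#' rmse(2.1, 2.2)          # 0.1
#' rmse(1:3, c(2, 2, 2))   # 0.8165
#' @export
rmse <- function(observed, simulated) {
  if (length(observed) == 0L) stop("empty input", call. = FALSE)
  if (length(observed) != length(simulated)) {
    stop("length mismatch: ", length(observed), " observed vs ",
         length(simulated), " simulated", call. = FALSE)
  }
  sqrt(mean((observed - simulated)^2))
}

#' Grade model performance from relative RMSE
#'
#' A simulation is graded on RMSE as a percentage of the observed mean:
#' excellent below 10%, good from 10% to 20%, acceptable/fair above 20% up
#' to 30%, poor beyond 30%. Boundary values at 10 and 20 belong to `good`
#' and 30 to `fair`, following the inclusive "10%-20%" / "20%-30%" reading
#' of the thresholds.
#'
#' @param rmse_value RMSE in the variable's units.
#' @param observed_mean mean of the observations (> 0), same units.
#' @return One of `"excellent"`, `"good"`, `"fair"`, `"poor"`.
#' @examples
#' grade(0.5, 10)   # 5%  -> excellent
#' grade(2.5, 10)   # 25% -> fair
#' @export
grade <- function(rmse_value, observed_mean) {
  if (observed_mean <= 0) stop("observed_mean must be > 0", call. = FALSE)
  if (rmse_value < 0) stop("rmse_value must be >= 0", call. = FALSE)
  pct <- 100 * rmse_value / observed_mean
  if (pct < 10) "excellent"
  else if (pct <= 20) "good"
  else if (pct <= 30) "fair"
  else "poor"
}

#' Observations table
#'
#' Observed values for model evaluation and calibration: a data.frame with
#' columns `variable` (one of `biomass`, `yield`, `phenology_day`),
#' `label` (e.g. year, or the phenology landmark name for
#' `phenology_day` rows: one of the names of [phenology_days()]) and
#' `value` (t/ha, or days).
#'
#' @param df data.frame with the three columns.
#' @return Validated data.frame of class `observations`.
#' @export
observations <- function(df) {
  need <- c("variable", "label", "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("observations missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ok <- c("biomass", "yield", "phenology_day")
  bad <- setdiff(unique(df$variable), ok)
  if (length(bad)) {
    stop("unknown observation variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$value < 0)) stop("observed values must be >= 0", call. = FALSE)
  df <- df[need]
  class(df) <- c("observations", "data.frame")
  df
}

# Simulated counterpart of each observation row. Phenology rows are read
# straight off the parameter calendar; biomass/yield from the run's finals.
.simulated_values <- function(obs, params, result) {
  ph <- phenology_days(params)
  vapply(seq_len(nrow(obs)), function(i) {
    v <- obs$variable[i]
    if (v == "biomass") result$finals$biomass
    else if (v == "yield") result$finals$yield
    else {
      lab <- obs$label[i]
      if (!lab %in% names(ph)) {
        stop("unknown phenology landmark '", lab, "'", call. = FALSE)
      }
      ph[[lab]]
    }
  }, numeric(1))
}

#' Evaluate a simulation against observations
#'
#' Computes RMSE and a performance grade per observed variable.
#'
#' @param obs an [observations()] table.
#' @param params the `crop_params` used for the run.
#' @param result the matching `simulation_result`.
#' @return data.frame with one row per variable: `variable`, `n`, `rmse`,
#'   `observed_mean`, `rmse_pct`, `grade`.
#' @export
evaluate_simulation <- function(obs, params, result) {
  obs <- observations(obs)
  sim <- .simulated_values(obs, params, result)
  out <- do.call(rbind, lapply(split(seq_len(nrow(obs)), obs$variable),
                               function(idx) {
    r <- rmse(obs$value[idx], sim[idx])
    m <- mean(obs$value[idx])
    data.frame(variable = obs$variable[idx[1]], n = length(idx), rmse = r,
               observed_mean = m, rmse_pct = 100 * r / m,
               grade = grade(r, m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
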