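#' Define a calibration step
#'
#' One step of the sequential calibration procedure: a named group of
#' parameters searched together (coordinate-wise) while all others are held
#' fixed.
#'
#' @param name group name (e.g. `life_cycle`, `canopy_rate`).
#' @param params named list; each element is `c(lower, upper)` bounds for
#'   one `crop_params` field.
#' @param integer character vector naming the parameters restricted to
#'   integer (calendar-day) values.
#' @param n_grid number of coarse grid points per parameter.
#' @return Object of class `calibration_step`.
#' @export
calibration_step <- function(name, params, integer = character(0),
                             n_grid = 15L) {
  if (!length(params)) stop("empty calibration step", call. = FALSE)
  for (p in names(params)) {
    b <- params[[p]]
    if (length(b) != 2L || b[1] >= b[2]) {
      stop("invalid bounds for ", p, call. = FALSE)
    }
  }
  structure(list(name = name, params = params, integer = integer,
                 n_grid = as.integer(n_grid)),
            class = "calibration_step")
}

#' Default sequential calibration steps
#'
#' The shipped step order follows the sequential (Boote-order) procedure
#' used to derive the hemp ideotypes from the sugarcane baseline: first the
#' crop life cycle (phenology calendar), then the rate of canopy
#' development, then maximum canopy cover together with the harvest index
#' (the canopy-cover analogue of a leaf-area-index step, since the engine
#' carries no LAI state), and lastly the onset and duration of
#' harvest-index buildup.
#'
#' @return Named list of [calibration_step()] objects, in order.
#' @export
default_calibration_steps <- function() {
  list(
    # cycle end first (senescence, then maturity): while the whole cycle is
    # out of range, candidate values for the earlier landmarks are either
    # unsimulable or violate the stage ordering
    life_cycle = calibration_step("life_cycle", list(
      d_senescence = c(60, 200), d_maturity = c(90, 250),
      d_flowering = c(30, 120), d_flowering_length = c(5, 40),
      d_emergence = c(1, 30), d_max_root = c(20, 120)
    ), integer = c("d_emergence", "d_flowering", "d_flowering_length",
                   "d_max_root", "d_senescence", "d_maturity")),
    canopy_rate = calibration_step("canopy_rate", list(
      cgc = c(0.05, 0.40)
    )),
    canopy_max_and_hi = calibration_step("canopy_max_and_hi", list(
      ccx = c(0.50, 0.99), hi_ref = c(0.05, 1.00)
    )),
    hi_buildup = calibration_step("hi_buildup", list(
      d_hi_buildup = c(5, 40), hi_onset_offset = c(0, 20)
    ), integer = c("d_hi_buildup", "hi_onset_offset"))
  )
}

# Calibration objective: RMSE per observed variable normalized by that
# variable's observed mean, averaged with equal weights; mixes t/ha and
# day-count observations on one dimensionless scale.
.calibration_objective <- function(params, obs, weather, soil, mgmt,
                                   control) {
  if (length(validate_parameters(params))) return(Inf)
  # candidates the forcing cannot support (e.g. a cycle longer than the
  # supplied weather) are treated as infeasible, not fatal
  result <- tryCatch(run_simulation(params, weather, soil, mgmt, control),
                     error = function(e) NULL)
  if (is.null(result)) return(Inf)
  sim <- .simulated_values(obs, params, result)
  groups <- split(seq_len(nrow(obs)), obs$variable)
  vals <- vapply(groups, function(idx) {
    m <- mean(obs$value[idx])
    if (m <= 0) return(NA_real_)
    s <- sim[idx]
    # an observed quantity the candidate cannot produce at all (e.g. an
    # observed flowering date for a crop without a flowering calendar)
    # incurs a large but finite per-element penalty, so the search keeps a
    # gradient on the observations it can produce
    s[is.na(s)] <- obs$value[idx][is.na(s)] + 10 * m
    rmse(obs$value[idx], s) / m
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# Candidate grid for one parameter: coarse pass over the bounds, then one
# refinement pass on an absolute lattice around the incumbent.
.coarse_grid <- function(bounds, is_int, n_grid) {
  g <- seq(bounds[1], bounds[2], length.out = n_grid)
  if (is_int) unique(round(g)) else g
}

.refine_grid <- function(center, bounds, is_int, n_grid, coarse_spacing) {
  center <- min(max(center, bounds[1]), bounds[2])
  lo <- max(bounds[1], center - coarse_spacing)
  hi <- min(bounds[2], center + coarse_spacing)
  if (lo > hi) return(numeric(0))
  if (is_int) {
    if (ceiling(lo) > floor(hi)) return(numeric(0))
    seq(ceiling(lo), floor(hi), by = 1)
  } else {
    fine <- 2 * coarse_spacing / (n_grid - 1)
    # snap to an absolute lattice anchored at the lower bound so repeated
    # calibrations revisit identical candidates
    k <- seq(ceiling((lo - bounds[1]) / fine), floor((hi - bounds[1]) / fine))
    bounds[1] + k * fine
  }
}

#' Sequential (Boote-order) calibration
#'
#' Adapts a baseline crop parameter set to observations by tuning parameter
#' groups strictly in the given order. Within a step each parameter is
#' searched by a deterministic coordinate grid (coarse pass over its
#' bounds, one refinement pass around the best value) while every other
#' parameter is held fixed; a candidate is accepted only when it strictly
#' lowers the objective, and ties resolve to the smaller parameter value.
#' The objective is the equal-weighted mean of per-variable RMSE normalized
#' by each variable's observed mean.
#'
#' @param base starting `crop_params` (e.g. the sugarcane baseline).
#' @param obs an [observations()] table (nonempty).
#' @param weather a `weather_series` covering the longest candidate season.
#' @param soil a `soil_profile`.
#' @param mgmt a [management_config()].
#' @param steps ordered list of [calibration_step()]s (default
#'   [default_calibration_steps()]).
#' @param control a [simulation_control()].
#' @return List with `params` (the calibrated set), `trace` (data.frame of
#'   every candidate tried: step, parameter, value, objective, accepted)
#'   and `objective` (final value, never above the initial one).
#' @export
calibrate_sequential <- function(base, obs, weather,
                                 soil = builtin_soil("clay_loam"),
                                 mgmt = management_config(),
                                 steps = default_calibration_steps(),
                                 control = simulation_control()) {
  obs <- observations(obs)
  if (!nrow(obs)) stop("empty observations", call. = FALSE)
  if (!length(steps)) stop("empty step list", call. = FALSE)
  for (st in steps) {
    bad <- setdiff(names(st$params),
                   c(setdiff(names(base), "stress_settings")))
    if (length(bad)) {
      stop("calibration step '", st$name, "' names unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  params <- base
  obj <- .calibration_objective(params, obs, weather, soil, mgmt, control)
  trace <- list()
  push <- function(step, parameter, value, objective, accepted) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, parameter = parameter, value = value,
      objective = objective, accepted = accepted, stringsAsFactors = FALSE)
  }

  try_grid <- function(step_name, pname, grid) {
    for (v in grid) {
      cand <- params
      cand[[pname]] <- if (pname %in% c("d_emergence", "d_max_root",
                                        "d_flowering", "d_flowering_length",
                                        "d_hi_buildup", "d_senescence",
                                        "d_maturity", "hi_onset_offset")) {
        as.integer(round(v))
      } else v
      o <- .calibration_objective(cand, obs, weather, soil, mgmt, control)
      accept <- is.finite(o) && o < obj - 1e-12
      push(step_name, pname, v, o, accept)
      if (accept) {
        params <<- cand
        obj <<- o
      }
    }
  }

  for (st in steps) {
    for (pname in names(st$params)) {
      bounds <- st$params[[pname]]
      is_int <- pname %in% st$integer
      coarse <- .coarse_grid(bounds, is_int, st$n_grid)
      spacing <- (bounds[2] - bounds[1]) / (st$n_grid - 1)
      try_grid(st$name, pname, coarse)
      center <- as.numeric(params[[pname]])
      if (!is.na(center)) {
        fine <- .refine_grid(center, bounds, is_int, st$n_grid, spacing)
        try_grid(st$name, pname, fine)
      }
    }
  }

  list(params = params,
       trace = do.call(rbind, trace),
       objective = obj)
}
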