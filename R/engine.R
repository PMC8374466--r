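#' Management configuration
#'
#' Planting date, plant population, optional irrigation schedule and the
#' initial soil-water condition. Defaults mirror the shipped hemp
#' ideotypes: planting 31 July, 140 000 plants/ha, rain-fed, soil at field
#' capacity.
#'
#' @param planting_date calendar date of sowing.
#' @param plant_population plants per hectare.
#' @param irrigation_schedule optional data.frame with columns `date`
#'   (Date) and `mm` (>= 0).
#' @param initial_soil_water initial water content as a fraction of field
#'   capacity (1 = at FC).
#' @return An object of class `management_config`.
#' @export
management_config <- function(planting_date = as.Date("2014-07-31"),
                              plant_population = 140000,
                              irrigation_schedule = NULL,
                              initial_soil_water = 1.0) {
  if (plant_population <= 0) stop("plant_population must be > 0", call. = FALSE)
  if (!is.null(irrigation_schedule)) {
    if (!all(c("date", "mm") %in% names(irrigation_schedule))) {
      stop("irrigation_schedule needs columns date, mm", call. = FALSE)
    }
    if (any(irrigation_schedule$mm < 0)) {
      stop("irrigation amounts must be >= 0", call. = FALSE)
    }
    irrigation_schedule$date <- as.Date(irrigation_schedule$date)
  }
  structure(list(planting_date = as.Date(planting_date),
                 plant_population = plant_population,
                 irrigation_schedule = irrigation_schedule,
                 initial_soil_water = initial_soil_water),
            class = "management_config")
}

#' Simulation control settings
#'
#' Numerical and submodel knobs with their defaults: maximum transpiration
#' coefficient `kc_tr_max` (1.10), maximum soil-evaporation coefficient
#' `ke_max` (1.10), readily evaporable water `rew_mm` (9 mm), whether the
#' production rule normalizes daily transpiration by ETo (`normalized`,
#' TRUE), and the consecutive-day run required to trigger stress-induced
#' early senescence (`early_sen_run`, 1).
#'
#' @export
simulation_control <- function(kc_tr_max = 1.10, ke_max = 1.10, rew_mm = 9,
                               normalized = TRUE, early_sen_run = 1L) {
  list(kc_tr_max = kc_tr_max, ke_max = ke_max, rew_mm = rew_mm,
       normalized = normalized, early_sen_run = as.integer(early_sen_run))
}

#' Run a full-season simulation
#'
#' Orchestrates the daily loop from sowing (DAS 0) to maturity. Within a
#' day the update order is: phenology and root depth, stress coefficients
#' from the previous end-of-day water state, canopy dynamics,
#' evapotranspiration partitioning and the water balance, then biomass and
#' harvest-index accrual from the transpiration actually extracted. This
#' ordering avoids same-day circular dependence between canopy, stress and
#' the water store.
#'
#' @param params a valid `crop_params` object.
#' @param weather a `weather_series` covering planting through
#'   planting + `d_maturity`.
#' @param soil a `soil_profile` (default the built-in clay loam).
#' @param mgmt a [management_config()].
#' @param control a [simulation_control()].
#' @return Object of class `simulation_result`: `$daily` (one row per DAS,
#'   `d_maturity + 1` rows: stage, cc, zr, theta, fluxes, stress
#'   coefficients, cumulative biomass t/ha and current HI), `$finals`
#'   (biomass t/ha, yield t/ha, harvest index, maturity date, cumulative
#'   water-balance residual in mm), and `$meta` (ideotype, soil texture,
#'   planting date, control settings).
#' @export
run_simulation <- function(params, weather,
                           soil = builtin_soil("clay_loam"),
                           mgmt = management_config(),
                           control = simulation_control()) {
  .assert_valid_params(params)
  n_days <- params$d_maturity
  dates <- mgmt$planting_date + 0:n_days
  wi <- match(dates, weather$date)
  if (anyNA(wi)) {
    stop("weather does not cover ", dates[1], " .. ", dates[n_days + 1],
         call. = FALSE)
  }
  irr <- numeric(n_days + 1)
  if (!is.null(mgmt$irrigation_schedule)) {
    m <- match(mgmt$irrigation_schedule$date, dates)
    ok <- !is.na(m)
    irr[m[ok]] <- irr[m[ok]] + mgmt$irrigation_schedule$mm[ok]
  }

  theta0 <- mgmt$initial_soil_water * soil$theta_fc
  sw <- init_soil_water(soil, zr = params$zr_min, theta_init = theta0)
  can <- canopy_init(params)
  prod <- production_init(params)
  settings <- params$stress_settings

  cols <- c("das", "cc", "zr", "theta", "infiltration", "drainage", "es",
            "tr", "ks_expansion", "ks_stomatal", "ks_senescence",
            "ks_aeration", "b", "hi")
  daily <- matrix(NA_real_, nrow = n_days + 1, ncol = length(cols),
                  dimnames = list(NULL, cols))
  stages <- character(n_days + 1)
  residual <- 0

  # DAS 0: initial condition row
  daily[1, ] <- c(0, can$cc, sw$zr, sw$theta, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0)
  stages[1] <- as.character(stage_at(0, params))

  for (das in seq_len(n_days)) {
    w <- weather[wi[das + 1], ]
    zr_new <- root_depth(das, params)

    depl <- relative_depletion(sw$theta, soil)
    ks <- stress_coefficients(depl, sw$theta, soil, settings)
    p_flw <- settings$p_upper_flowering
    ks_flw <- if (is.na(p_flw) || depl <= p_flw) 1 else {
      max(0, (1 - depl) / max(1e-12, 1 - p_flw))
    }

    can <- canopy_step(can, params, ks$ks_expansion, ks$ks_senescence,
                       control$early_sen_run)
    cc_eff <- cc_effective(can$cc)
    tr_demand <- transpiration_demand(can$cc, w$eto, ks$ks_stomatal,
                                      ks$ks_aeration, control$kc_tr_max)

    step <- water_balance_step(sw, soil,
                               water_in = w$rain + irr[das + 1],
                               eto = w$eto, cc = cc_eff, zr_new = zr_new,
                               tr_demand = tr_demand,
                               ke_max = control$ke_max,
                               rew = control$rew_mm)
    sw <- step$state
    fl <- step$fluxes
    residual <- residual + abs(fl$delta_storage -
                                 (fl$root_zone_gain + fl$infiltration -
                                    fl$drainage - fl$es - fl$tr))

    if (fl$tr > 0) {
      prod$b <- prod$b + biomass_increment(params$wp_normalized, fl$tr,
                                           w$eto, control$normalized)
      prod$tr_cum_norm <- prod$tr_cum_norm +
        if (control$normalized) fl$tr / w$eto else fl$tr
    }
    prod <- harvest_index_step(prod, params, das, ks, ks_flw)

    daily[das + 1, ] <- c(das, can$cc, sw$zr, sw$theta, fl$infiltration,
                          fl$drainage, fl$es, fl$tr, ks$ks_expansion,
                          ks$ks_stomatal, ks$ks_senescence, ks$ks_aeration,
                          prod$b / 100, prod$hi)
    stages[das + 1] <- as.character(stage_at(das, params))
  }

  daily_df <- as.data.frame(daily)
  daily_df$stage <- factor(stages, levels = stage_levels())
  daily_df$date <- dates
  daily_df <- daily_df[c("das", "date", "stage",
                         setdiff(cols, "das"))]

  biomass_t_ha <- prod$b / 100
  structure(list(
    daily = daily_df,
    finals = list(biomass = biomass_t_ha,
                  yield = yield_final(biomass_t_ha, prod$hi),
                  harvest_index = prod$hi,
                  tr_cum_norm = prod$tr_cum_norm,
                  maturity_date = dates[n_days + 1],
                  water_balance_residual_mm = residual),
    meta = list(ideotype = params$name, soil = soil$texture_label,
                planting_date = mgmt$planting_date, control = control)
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", x$meta$ideotype, " on ", x$meta$soil,
      ", planted ", format(x$meta$planting_date), "\n", sep = "")
  cat(sprintf("  biomass %.2f t/ha, yield %.2f t/ha (HI %.3f), mature %s\n",
              x$finals$biomass, x$finals$yield, x$finals$harvest_index,
              format(x$finals$maturity_date)))
  cat(sprintf("  water-balance residual %.2e mm over %d days\n",
              x$finals$water_balance_residual_mm, nrow(x$daily) - 1L))
  invisible(x)
}

#' Phenology landmarks of a parameter set
#'
#' Named day counts used when comparing simulated phenology with observed
#' stage durations.
#' @param params a `crop_params` object.
#' @return Named numeric vector (days after sowing, or stage lengths in
#'   days for `flowering_length` and `hi_buildup_length`).
#' @export
phenology_days <- function(params) {
  c(emergence = as.numeric(params$d_emergence),
    max_root = as.numeric(params$d_max_root),
    flowering = as.numeric(params$d_flowering),
    flowering_length = as.numeric(params$d_flowering_length),
    hi_buildup_length = as.numeric(params$d_hi_buildup),
    senescence = as.numeric(params$d_senescence),
    maturity = as.numeric(params$d_maturity))
}
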