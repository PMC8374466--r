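#' Soil hydraulic profile
#'
#' A homogeneous single-store description of the root zone: volumetric water
#' contents at permanent wilting point, field capacity and saturation, the
#' saturated hydraulic conductivity, and a drainage coefficient `tau` in
#' (0, 1] giving the fraction of the above-field-capacity excess that
#' drains per day.
#'
#' @param texture_label free-text texture class.
#' @param theta_pwp,theta_fc,theta_sat volumetric fractions,
#'   `0 < pwp < fc < sat < 1`.
#' @param ksat saturated hydraulic conductivity, mm/d.
#' @param drainage_tau daily drainage fraction of the excess above FC.
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(texture_label, theta_pwp, theta_fc, theta_sat,
                         ksat, drainage_tau = 0.75) {
  if (!(theta_pwp > 0 && theta_pwp < theta_fc && theta_fc < theta_sat &&
        theta_sat < 1)) {
    stop("require 0 < theta_pwp < theta_fc < theta_sat < 1", call. = FALSE)
  }
  if (ksat <= 0) stop("ksat must be > 0", call. = FALSE)
  if (drainage_tau <= 0 || drainage_tau > 1) {
    stop("drainage_tau must be in (0, 1]", call. = FALSE)
  }
  structure(list(texture_label = texture_label,
                 theta_pwp = theta_pwp, theta_fc = theta_fc,
                 theta_sat = theta_sat, ksat = ksat,
                 drainage_tau = drainage_tau),
            class = "soil_profile")
}

#' Built-in soil profiles
#'
#' `clay_loam` is the default: PWP 0.23, FC 0.39, SAT 0.50 (volumetric),
#' Ksat 125 mm/d -- the model family's standard clay-loam hydraulics.
#'
#' @param name currently only `"clay_loam"`.
#' @export
builtin_soil <- function(name = "clay_loam") {
  if (!identical(name, "clay_loam")) {
    stop("unknown soil '", name, "'; valid names: clay_loam", call. = FALSE)
  }
  soil_profile("clay loam", theta_pwp = 0.23, theta_fc = 0.39,
               theta_sat = 0.50, ksat = 125, drainage_tau = 0.75)
}

#' Read / write a soil profile key-value file
#'
#' Format: one `key = value` per line (`texture`, `pwp`, `fc`, `sat`,
#' `ksat`, `tau`), `#` comments.
#' @param path file path.
#' @export
read_soil <- function(path) {
  if (!file.exists(path)) stop("soil file not found: ", path, call. = FALSE)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- vapply(kv, `[`, "", 2L)
  names(vals) <- vapply(kv, `[`, "", 1L)
  need <- c("texture", "pwp", "fc", "sat", "ksat")
  missing <- setdiff(need, names(vals))
  if (length(missing)) {
    stop("missing soil key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  soil_profile(vals[["texture"]],
               theta_pwp = as.numeric(vals[["pwp"]]),
               theta_fc = as.numeric(vals[["fc"]]),
               theta_sat = as.numeric(vals[["sat"]]),
               ksat = as.numeric(vals[["ksat"]]),
               drainage_tau = if ("tau" %in% names(vals))
                 as.numeric(vals[["tau"]]) else 0.75)
}

#' @rdname read_soil
#' @param profile a `soil_profile`.
#' @export
write_soil <- function(profile, path) {
  writeLines(c(
    "# ideocrop soil profile",
    paste("texture =", profile$texture_label),
    paste("pwp =", format(profile$theta_pwp, digits = 17)),
    paste("fc =", format(profile$theta_fc, digits = 17)),
    paste("sat =", format(profile$theta_sat, digits = 17)),
    paste("ksat =", format(profile$ksat, digits = 17)),
    paste("tau =", format(profile$drainage_tau, digits = 17))
  ), path)
  invisible(path)
}

#' Initialize the root-zone water state
#'
#' @param profile a `soil_profile`.
#' @param zr initial root depth, m.
#' @param theta_init initial volumetric water content (also used for soil
#'   newly reached by root deepening); default field capacity.
#' @return An object of class `soil_water_state` with fields `theta`
#'   (volumetric fraction), `zr` (m), `theta_init` and
#'   `surface_evap_stage` (mm extracted since the surface was last wetted).
#' @export
init_soil_water <- function(profile, zr, theta_init = profile$theta_fc) {
  theta_init <- min(max(theta_init, 0), profile$theta_sat)
  structure(list(theta = theta_init, zr = zr, theta_init = theta_init,
                 surface_evap_stage = 0),
            class = "soil_water_state")
}

#' Water-stress coefficients
#'
#' The four multiplicative stress coefficients of the water-driven model:
#' canopy expansion, stomatal closure, early canopy senescence and
#' aeration. The first three respond to relative root-zone depletion
#' (fraction of total available water FC - PWP already used): Ks = 1 below
#' the process's `p_upper`, 0 at or beyond its `p_lower`, linear in
#' between. Aeration stress responds to waterlogging: Ks falls linearly
#' from 1 at `theta_sat - margin` to 0 at saturation.
#'
#' @param depletion_rel relative depletion in `[0, 1]`.
#' @param theta current volumetric water content.
#' @param profile a `soil_profile`.
#' @param settings a [stress_settings()] object.
#' @return List of class `stress_coefficients` with `ks_expansion`,
#'   `ks_stomatal`, `ks_senescence`, `ks_aeration`, all in `[0, 1]`.
#' @export
stress_coefficients <- function(depletion_rel, theta, profile, settings) {
  if (depletion_rel < 0 || depletion_rel > 1) {
    stop("depletion_rel outside [0, 1]", call. = FALSE)
  }
  ks_lin <- function(p_upper, p_lower) {
    if (is.na(p_upper)) return(1)
    if (depletion_rel <= p_upper) 1
    else if (depletion_rel >= p_lower) 0
    else (p_lower - depletion_rel) / (p_lower - p_upper)
  }
  thr <- profile$theta_sat - settings$aeration_margin
  ks_aer <- if (theta <= thr) 1 else {
    max(0, (profile$theta_sat - theta) / settings$aeration_margin)
  }
  structure(list(
    ks_expansion = ks_lin(settings$p_upper_expansion,
                          settings$p_lower_expansion),
    ks_stomatal = ks_lin(settings$p_upper_stomatal,
                         settings$p_lower_stomatal),
    ks_senescence = ks_lin(settings$p_upper_senescence,
                           settings$p_lower_senescence),
    ks_aeration = ks_aer
  ), class = "stress_coefficients")
}

#' One daily step of the root-zone water balance
#'
#' Single-bucket accounting in this order: root-zone deepening (new soil
#' enters at the initialization content), infiltration of rain plus
#' irrigation up to available pore space (the remainder is reported as
#' `non_infiltrated`; no runoff routing), drainage of a `tau` fraction of
#' the excess above field capacity capped at Ksat, soil evaporation (stage
#' one at `ke_max * (1 - cc) * eto` until the readily-evaporable-water
#' budget is spent, then square-root-of-time decay), and transpiration
#' extraction capped by the extractable store above wilting point. The
#' daily mass balance closes exactly:
#' `delta_storage = root_zone_gain + infiltration - drainage - es - tr`.
#'
#' @param state a `soil_water_state`.
#' @param profile a `soil_profile`.
#' @param water_in rain plus irrigation, mm.
#' @param eto reference evapotranspiration, mm.
#' @param cc effective canopy cover fraction shading the soil.
#' @param zr_new root depth after today's deepening, m (`>= state$zr`).
#' @param tr_demand transpiration demand, mm.
#' @param ke_max maximum soil-evaporation coefficient.
#' @param rew readily evaporable water, mm (stage-one budget).
#' @return List with `state` (updated) and `fluxes` (mm): `infiltration`,
#'   `non_infiltrated`, `drainage`, `es`, `tr`, `tr_potential_supply`,
#'   `root_zone_gain`, `delta_storage`.
#' @export
water_balance_step <- function(state, profile, water_in, eto, cc, zr_new,
                               tr_demand = 0, ke_max = 1.10, rew = 9) {
  if (water_in < 0 || eto < 0 || tr_demand < 0) {
    stop("negative flux input", call. = FALSE)
  }
  if (zr_new < state$zr - 1e-12) stop("root zone cannot shrink", call. = FALSE)
  mm <- function(theta, zr) theta * zr * 1000
  storage0 <- mm(state$theta, state$zr)

  # root deepening: new layer enters at the initialization content
  gain <- mm(state$theta_init, zr_new) - mm(state$theta_init, state$zr)
  storage <- storage0 + gain
  zr <- zr_new
  cap_sat <- mm(profile$theta_sat, zr)
  cap_fc <- mm(profile$theta_fc, zr)

  # infiltration up to pore space
  infil <- min(water_in, cap_sat - storage)
  infil <- max(infil, 0)
  non_infil <- water_in - infil
  storage <- storage + infil

  # drainage of excess above field capacity
  drainage <- 0
  if (storage > cap_fc) {
    drainage <- min(profile$drainage_tau * (storage - cap_fc), profile$ksat)
  }
  storage <- storage - drainage

  # soil evaporation: two-stage
  es_pot <- ke_max * max(0, 1 - cc) * eto
  w <- state$surface_evap_stage
  es_rate <- if (w < rew) es_pot else es_pot * sqrt(rew / w)
  # evaporable store: above half of wilting point
  es_floor <- mm(profile$theta_pwp / 2, zr)
  es <- min(es_rate, max(0, storage - es_floor))
  storage <- storage - es

  # transpiration: demand capped by extractable water above wilting point
  tr_floor <- mm(profile$theta_pwp, zr)
  tr_supply <- max(0, storage - tr_floor)
  tr <- min(tr_demand, tr_supply)
  storage <- storage - tr

  # surface wetting resets the evaporation-stage tracker
  w_new <- max(0, w + es - infil)

  new_state <- state
  new_state$theta <- storage / (zr * 1000)
  new_state$zr <- zr
  new_state$surface_evap_stage <- w_new

  list(state = new_state,
       fluxes = list(infiltration = infil, non_infiltrated = non_infil,
                     drainage = drainage, es = es, tr = tr,
                     tr_potential_supply = tr_supply,
                     root_zone_gain = gain,
                     delta_storage = storage - storage0))
}

#' Relative root-zone depletion
#'
#' Fraction of total available water (FC - PWP) depleted; 0 at or above
#' field capacity, 1 at or below wilting point.
#' @param theta volumetric water content.
#' @param profile a `soil_profile`.
#' @export
relative_depletion <- function(theta, profile) {
  d <- (profile$theta_fc - theta) / (profile$theta_fc - profile$theta_pwp)
  min(1, max(0, d))
}
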