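#' Effective canopy cover for transpiration and evaporation
#'
#' Convexity adjustment of the geometric canopy cover accounting for
#' radiation intercepted at low and micro-advection at high cover:
#' `cc* = 1.72 cc - cc^2 + 0.30 cc^3`, clamped to `[0, 1]`.
#'
#' @param cc canopy cover fraction.
#' @export
cc_effective <- function(cc) {
  pmin(1, pmax(0, 1.72 * cc - cc^2 + 0.30 * cc^3))
}

#' Daily crop transpiration demand
#'
#' `tr = ks_stomatal * ks_aeration * kc_tr_max * cc* * eto`, the canopy's
#' water demand before the soil supply cap is applied.
#'
#' @param cc canopy cover fraction (geometric; the convexity adjustment is
#'   applied internally).
#' @param eto reference evapotranspiration, mm.
#' @param ks_stomatal,ks_aeration stress coefficients in `[0, 1]`.
#' @param kc_tr_max maximum crop transpiration coefficient (default 1.10).
#' @return Transpiration demand, mm.
#' @export
transpiration_demand <- function(cc, eto, ks_stomatal = 1, ks_aeration = 1,
                                 kc_tr_max = 1.10) {
  ks_stomatal * ks_aeration * kc_tr_max * cc_effective(cc) * eto
}

#' Daily biomass increment from normalized transpiration
#'
#' The core water-driven production rule: above-ground biomass accumulates
#' as normalized water productivity times cumulative normalized
#' transpiration, `B = WP* x sum(Tr / ETo)`. The daily increment is
#' `wp_normalized * tr / eto` (g m^-2); normalizing each day's
#' transpiration by that day's ETo is what makes WP* transferable across
#' climates. A raw (unnormalized) mode is available for comparison via
#' `normalized = FALSE`, where the increment is `wp_normalized * tr` per mm.
#'
#' @param wp_normalized normalized water productivity, g m^-2.
#' @param tr actual transpiration, mm.
#' @param eto reference evapotranspiration, mm (must be > 0 when `tr > 0`
#'   in normalized mode).
#' @param normalized normalize by ETo (default TRUE).
#' @return Biomass increment, g m^-2; zero iff `tr` is zero.
#' @export
biomass_increment <- function(wp_normalized, tr, eto, normalized = TRUE) {
  if (tr < 0) stop("tr must be >= 0", call. = FALSE)
  if (tr == 0) return(0)
  if (!normalized) return(wp_normalized * tr)
  if (eto <= 0) {
    stop("undefined normalization: tr > 0 with eto = 0", call. = FALSE)
  }
  wp_normalized * tr / eto
}

#' Initial production state
#' @param params a `crop_params` object.
#' @return List of class `production_state`: cumulative biomass `b`
#'   (g m^-2), current harvest index `hi`, cumulative normalized
#'   transpiration `tr_cum_norm`, and the stress-adjustment accumulators.
#' @export
production_init <- function(params) {
  structure(list(b = 0, hi = 0, tr_cum_norm = 0,
                 hi_days_done = 0L,
                 adj_pos_veg = 0, adj_pos_leaf = 0, adj_neg_stom = 0,
                 flowering_penalty = 0),
            class = "production_state")
}

#' One daily step of harvest-index buildup
#'
#' HI is zero before buildup onset (flowering onset plus the configurable
#' offset; emergence for crops without a flowering calendar). From the day
#' after onset it increases linearly to `hi_ref` over `d_hi_buildup` days,
#' after which it is frozen. Water stress adjusts the trajectory
#' multiplicatively, accumulated pro-rata over the relevant windows and
#' capped by the category factor (none 0%, moderate 10%, strong 20%):
#' upward for limited vegetative growth (expansion stress before
#' flowering) and for leaf-expansion stress during buildup, downward for
#' stomatal closure during buildup. Severe depletion during the flowering
#' window (beyond `p_upper_flowering`) reduces HI through a pollination
#' failure penalty.
#'
#' @param state a `production_state`.
#' @param params a `crop_params` object.
#' @param das days after sowing of the day being applied.
#' @param stress a `stress_coefficients` object for the day.
#' @param ks_flowering pollination stress coefficient in `[0, 1]` (1 = no
#'   flowering stress).
#' @return Updated `production_state`; `$hi` is the current adjusted HI.
#' @export
harvest_index_step <- function(state, params, das, stress,
                               ks_flowering = 1) {
  s <- params$stress_settings
  caps <- s$hi_adjustment_caps
  onset <- .hi_onset(params)
  nb <- params$d_hi_buildup

  # positive adjustment potential from restrained vegetative growth
  if (!is.na(params$d_flowering) &&
      das > params$d_emergence && das <= params$d_flowering) {
    nveg <- params$d_flowering - params$d_emergence
    state$adj_pos_veg <- min(caps[[s$hi_pos_veg]],
                             state$adj_pos_veg +
                               caps[[s$hi_pos_veg]] / nveg *
                               (1 - stress$ks_expansion))
  }

  # flowering-window pollination stress
  if (!is.na(params$d_flowering) && !is.na(params$d_flowering_length) &&
      das > params$d_flowering &&
      das <= params$d_flowering + params$d_flowering_length) {
    state$flowering_penalty <- min(1,
      state$flowering_penalty +
        (1 - ks_flowering) / params$d_flowering_length)
  }

  # linear buildup with stress accumulators
  if (das > onset && state$hi_days_done < nb) {
    state$hi_days_done <- state$hi_days_done + 1L
    state$adj_pos_leaf <- min(caps[[s$hi_pos_leaf]],
                              state$adj_pos_leaf +
                                caps[[s$hi_pos_leaf]] / nb *
                                (1 - stress$ks_expansion))
    state$adj_neg_stom <- min(caps[[s$hi_neg_stomatal]],
                              state$adj_neg_stom +
                                caps[[s$hi_neg_stomatal]] / nb *
                                (1 - stress$ks_stomatal))
  }

  hi_lin <- params$hi_ref * state$hi_days_done / nb
  adj <- 1 + state$adj_pos_veg + state$adj_pos_leaf - state$adj_neg_stom
  hi <- hi_lin * adj * (1 - state$flowering_penalty)
  # harvestable fraction cannot exceed the whole biomass
  max_cap <- min(params$hi_ref * (1 + max(caps)), 1)
  state$hi <- min(max(hi, 0), max_cap)
  state
}

#' Final yield from biomass and harvest index
#'
#' `Y = B x HI`. Units follow the biomass argument (t/ha throughout the
#' engine; 1 t/ha = 100 g m^-2).
#'
#' @param b final above-ground biomass.
#' @param hi harvest index fraction in `[0, 1.2]`.
#' @export
yield_final <- function(b, hi) {
  if (b < 0) stop("biomass must be >= 0", call. = FALSE)
  if (hi < 0 || hi > 1.2) stop("hi outside [0, 1.2]", call. = FALSE)
  b * hi
}
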