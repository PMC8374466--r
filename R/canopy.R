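#' Unstressed canopy cover as a closed form
#'
#' Canopy development under no stress follows the classic two-piece
#' exponential: `cc0 * exp(cgc * t)` while cover is below half of `ccx`
#' (exponential growth), then `ccx - 0.25 * (ccx^2 / cc0) * exp(-cgc * t)`
#' (exponential approach to the maximum). The two pieces join continuously
#' at `cc = ccx / 2`.
#'
#' @param t days since emergence (>= 0, vectorized).
#' @param params a `crop_params` object.
#' @return Canopy cover fraction in `[cc0, ccx]`.
#' @export
canopy_cover_unstressed <- function(t, params) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  cc0 <- params$cc0; ccx <- params$ccx; cgc <- params$cgc
  grow <- cc0 * exp(cgc * t)
  decayed <- ccx - 0.25 * (ccx^2 / cc0) * exp(-cgc * t)
  pmin(ccx, ifelse(grow <= ccx / 2, grow, pmax(decayed, ccx / 2)))
}

# Inverse of the growth closed form: virtual time since emergence at which
# unstressed cover equals cc. Used to re-anchor the discrete daily step so
# iterated steps agree with the closed form to floating point.
.canopy_growth_time <- function(cc, params) {
  cc0 <- params$cc0; ccx <- params$ccx; cgc <- params$cgc
  if (cc <= ccx / 2) {
    log(cc / cc0) / cgc
  } else {
    -log(4 * cc0 * (ccx - cc) / ccx^2) / cgc
  }
}

# Senescence decline: relative decay anchored at the cover when decline
# began, cc_on * (1 - 0.05 * (exp((cdc / ccx) * t) - 1)), floored at 0.
.canopy_decline <- function(t, cc_on, params) {
  max(0, cc_on * (1 - 0.05 * (exp((params$cdc / params$ccx) * t) - 1)))
}

.canopy_decline_time <- function(cc, cc_on, params) {
  # inverse of .canopy_decline for cc in (0, cc_on]
  (params$ccx / params$cdc) * log(1 + 20 * (1 - cc / cc_on))
}

#' Initial canopy state at sowing
#' @param params a `crop_params` object.
#' @return List of class `canopy_state`: `cc`, `das`, `senescing`, and the
#'   decline anchor fields used once senescence begins.
#' @export
canopy_init <- function(params) {
  structure(list(cc = 0, das = 0L, senescing = FALSE,
                 cc_at_sen = NA_real_, t_sen = NA_real_,
                 stress_run = 0L),
            class = "canopy_state")
}

#' One daily step of canopy-cover dynamics
#'
#' Advances the canopy by one day. Before emergence cover is zero; at
#' emergence it jumps to `cc0`. During growth the closed form is
#' re-anchored at the current cover and advanced by `ks_expansion` days of
#' virtual time, so the effective growth rate is `ks_expansion * cgc` and
#' iterated unstressed steps reproduce [canopy_cover_unstressed()] exactly.
#' Decline begins at `d_senescence`, or earlier when `ks_senescence < 1`
#' persists for `early_sen_run` consecutive days (stress-triggered early
#' senescence advances the decline clock by `1 - ks_senescence` days, and
#' growth resumes if the stress lifts before calendar senescence).
#'
#' @param state a `canopy_state`.
#' @param params a `crop_params` object.
#' @param ks_expansion,ks_senescence stress coefficients in `[0, 1]`.
#' @param early_sen_run consecutive stressed days required to trigger early
#'   senescence (default 1).
#' @return The advanced `canopy_state` (with `das` incremented).
#' @export
canopy_step <- function(state, params, ks_expansion = 1, ks_senescence = 1,
                        early_sen_run = 1L) {
  if (ks_expansion < 0 || ks_expansion > 1 ||
      ks_senescence < 0 || ks_senescence > 1) {
    stop("stress coefficients must be in [0, 1]", call. = FALSE)
  }
  das <- state$das + 1L
  state$das <- das

  if (das < params$d_emergence) {
    state$cc <- 0
    return(state)
  }
  if (das == params$d_emergence) {
    state$cc <- params$cc0
    return(state)
  }

  natural_sen <- das >= params$d_senescence
  state$stress_run <- if (ks_senescence < 1) state$stress_run + 1L else 0L
  early_sen <- !natural_sen && state$stress_run >= early_sen_run

  if (natural_sen || early_sen) {
    if (!state$senescing || is.na(state$cc_at_sen)) {
      state$senescing <- TRUE
      state$cc_at_sen <- state$cc
      state$t_sen <- 0
    }
    dt <- if (natural_sen) 1 else (1 - ks_senescence)
    state$t_sen <- state$t_sen + dt
    state$cc <- .canopy_decline(state$t_sen, state$cc_at_sen, params)
    return(state)
  }

  # growth phase (possibly resuming after a lifted early-senescence spell)
  state$senescing <- FALSE
  state$cc_at_sen <- NA_real_
  state$t_sen <- NA_real_
  if (state$cc <= 0) {
    state$cc <- params$cc0  # re-establishment floor
  }
  if (ks_expansion > 0 && state$cc < params$ccx - 1e-12) {
    # cover below cc0 (possible after a stress-decline spell) re-anchors at
    # the start of the growth curve
    t <- max(0, .canopy_growth_time(state$cc, params))
    state$cc <- canopy_cover_unstressed(t + ks_expansion, params)
  }
  state
}
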