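#' Phenological stages
#'
#' Development is tracked on calendar days after sowing (DAS), the scale on
#' which the shipped ideotypes are parameterized. Stages occur in a fixed
#' order; each calendar boundary belongs to the later stage (day
#' `d_emergence` is the first vegetative day) and `mature` is absorbing.
#'
#' @return Character vector of stage names in developmental order.
#' @export
stage_levels <- function() {
  c("pre_emergence", "vegetative", "flowering", "hi_buildup",
    "senescence", "mature")
}

#' Developmental stage at a given day after sowing
#'
#' Piecewise-constant mapping from DAS to stage using the parameter set's
#' calendar thresholds. Flowering and HI buildup overlap in time; so that
#' the reported stage never moves backward, the stage switches to
#' `hi_buildup` on the first day buildup accrues (the day after onset) and
#' keeps that label until senescence even though flowering may still be in
#' progress. Crops without a flowering calendar (e.g. the sugarcane
#' baseline) skip the flowering stage and begin HI buildup at emergence.
#'
#' @param das days after sowing (vectorized, >= 0).
#' @param params a `crop_params` object.
#' @return Factor with levels [stage_levels()].
#' @export
stage_at <- function(das, params) {
  if (any(das < 0)) stop("das must be >= 0", call. = FALSE)
  onset <- .hi_onset(params)
  flowering <- if (is.na(params$d_flowering)) Inf else params$d_flowering
  stage <- ifelse(das >= params$d_maturity, "mature",
           ifelse(das >= params$d_senescence, "senescence",
           ifelse(das > onset, "hi_buildup",
           ifelse(das >= flowering, "flowering",
           ifelse(das >= params$d_emergence, "vegetative",
                  "pre_emergence")))))
  factor(stage, levels = stage_levels())
}

# HI buildup onset: flowering onset plus a configurable offset; falls back
# to emergence when the crop has no flowering calendar.
.hi_onset <- function(params) {
  base <- if (is.na(params$d_flowering)) params$d_emergence else params$d_flowering
  base + params$hi_onset_offset
}

#' Effective rooting depth at a given day after sowing
#'
#' `zr_min` up to emergence, then linear deepening to `zr_max` at
#' `d_max_root`, constant thereafter. Continuous and nondecreasing.
#'
#' @inheritParams stage_at
#' @return Rooting depth, m (vectorized).
#' @export
root_depth <- function(das, params) {
  if (any(das < 0)) stop("das must be >= 0", call. = FALSE)
  e <- params$d_emergence
  m <- params$d_max_root
  if (m <= e) return(rep(params$zr_max, length(das)))
  frac <- pmin(1, pmax(0, (das - e) / (m - e)))
  params$zr_min + frac * (params$zr_max - params$zr_min)
}

#' Growing degree days for one day
#'
#' Daily thermal time from the mean of Tmax and Tmin, capped at the cut-off
#' temperature and floored at zero below the base temperature:
#' `max(0, min((tmax + tmin)/2, t_upper) - t_base)`. Provided for GDD-mode
#' work; the shipped ideotypes run on calendar days.
#'
#' @param t_max,t_min daily extremes, deg C (`t_max >= t_min`).
#' @param t_base,t_upper base and cut-off temperatures, deg C.
#' @return Degree-days (deg C day), never negative.
#' @export
gdd <- function(t_max, t_min, t_base, t_upper) {
  if (t_base >= t_upper) stop("t_base must be below t_upper", call. = FALSE)
  if (any(t_max < t_min)) stop("t_max < t_min", call. = FALSE)
  pmax(0, pmin((t_max + t_min) / 2, t_upper) - t_base)
}
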