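#' Crop parameter sets ("ideotypes")
#'
#' A crop parameter set bundles everything the simulation engine needs to
#' know about a crop: phenology calendar (calendar days after sowing),
#' canopy coefficients, rooting depths, normalized water productivity,
#' reference harvest index, and water-stress response settings.
#'
#' Percent-valued quantities (maximum canopy cover, harvest index) are held
#' internally as fractions in (0, 1]. The initial canopy cover `cc0` is not
#' an independent input: it is derived from the plant population and a
#' per-seedling ground cover (default 5 cm^2 per plant), so 140 000
#' plants/ha gives cc0 = 14 m^-2 x 5e-4 m^2 = 0.007.
#'
#' @param name identifier string.
#' @param t_base,t_upper base and cut-off temperature, deg C.
#' @param ccx maximum canopy cover, fraction.
#' @param cgc canopy growth coefficient, fraction soil cover per day.
#' @param cdc canopy decline coefficient, fraction per day.
#' @param zr_min,zr_max minimum and maximum effective rooting depth, m.
#' @param d_emergence,d_max_root,d_flowering,d_senescence,d_maturity
#'   calendar days after sowing to each phenological landmark. `d_flowering`
#'   may be `NA` for crops without a determinate flowering stage (harvest
#'   index buildup then starts at emergence).
#' @param d_flowering_length length of the flowering stage, days (`NA` when
#'   flowering is undefined).
#' @param d_hi_buildup length of harvest-index buildup, days.
#' @param wp_normalized normalized water productivity, g m^-2.
#' @param hi_ref reference harvest index, fraction.
#' @param plant_population plants per hectare.
#' @param seedling_cover ground cover of one seedling, m^2 (default 5e-4).
#' @param cc0 initial canopy cover at emergence, fraction; computed from
#'   `plant_population` and `seedling_cover` when missing.
#' @param stress_settings a [stress_settings()] object.
#' @param hi_onset_offset days after `d_flowering` at which harvest-index
#'   buildup begins (default 0).
#'
#' @return An object of class `crop_params` (a named list).
#' @seealso [builtin_ideotype()], [validate_parameters()],
#'   [load_crop_parameters()]
#' @export
crop_parameter_set <- function(name,
                               t_base, t_upper,
                               ccx, cgc, cdc,
                               zr_min, zr_max,
                               d_emergence, d_max_root,
                               d_flowering, d_flowering_length,
                               d_hi_buildup, d_senescence, d_maturity,
                               wp_normalized, hi_ref,
                               plant_population,
                               seedling_cover = 5e-4,
                               cc0 = NULL,
                               stress_settings = default_stress_settings(),
                               hi_onset_offset = 0) {
  if (is.null(cc0)) {
    cc0 <- plant_population / 1e4 * seedling_cover  # plants m^-2 x m^2
  }
  p <- structure(list(
    name = as.character(name),
    t_base = as.numeric(t_base), t_upper = as.numeric(t_upper),
    cc0 = as.numeric(cc0), ccx = as.numeric(ccx),
    cgc = as.numeric(cgc), cdc = as.numeric(cdc),
    zr_min = as.numeric(zr_min), zr_max = as.numeric(zr_max),
    d_emergence = as.integer(d_emergence),
    d_max_root = as.integer(d_max_root),
    d_flowering = suppressWarnings(as.integer(d_flowering)),
    d_flowering_length = suppressWarnings(as.integer(d_flowering_length)),
    d_hi_buildup = as.integer(d_hi_buildup),
    d_senescence = as.integer(d_senescence),
    d_maturity = as.integer(d_maturity),
    wp_normalized = as.numeric(wp_normalized),
    hi_ref = as.numeric(hi_ref),
    plant_population = as.numeric(plant_population),
    seedling_cover = as.numeric(seedling_cover),
    hi_onset_offset = as.integer(hi_onset_offset),
    stress_settings = stress_settings
  ), class = "crop_params")
  p
}

#' Water-stress response settings
#'
#' Categorical harvest-index stress responses and the numeric root-zone
#' depletion thresholds that drive the four stress coefficients
#' (canopy expansion, stomatal closure, early senescence, aeration).
#' Depletion is expressed as the fraction of total available water
#' (FC - PWP over the root zone) already used: 0 = at field capacity,
#' 1 = at wilting point. A coefficient is 1 below its `p_upper`, 0 at or
#' beyond its `p_lower`, linear in between.
#'
#' Categories map to numeric defaults: the stomatal threshold `p_upper_stomatal`
#' defaults to 0.50 for a `moderate` stomatal HI response and 0.35 for
#' `strong`; harvest-index adjustment caps are 0 / 10% / 20% for
#' none / moderate / strong; `sensitive` aeration places the anaerobiosis
#' margin 5 vol-% below saturation (moderate 3%, tolerant 1%). All defaults
#' are overridable.
#'
#' @param hi_pos_veg,hi_pos_leaf,hi_neg_stomatal one of `"none"`,
#'   `"moderate"`, `"strong"`: positive HI response to limited vegetative
#'   growth, positive response to leaf-expansion stress, negative response
#'   to stomatal closure.
#' @param aeration one of `"tolerant"`, `"moderate"`, `"sensitive"`.
#' @param p_upper_flowering depletion threshold for flowering (pollination)
#'   stress in `[0,1]`, or `NA` when flowering stress is not modelled.
#' @param p_upper_expansion,p_lower_expansion,p_upper_stomatal,p_upper_senescence
#'   numeric depletion thresholds in `[0,1]`; `p_upper_stomatal = NULL`
#'   takes the category default.
#' @return An object of class `stress_settings`.
#' @export
stress_settings <- function(hi_pos_veg = "moderate",
                            hi_pos_leaf = "moderate",
                            hi_neg_stomatal = "moderate",
                            aeration = "sensitive",
                            p_upper_flowering = NA_real_,
                            p_upper_expansion = 0.20,
                            p_lower_expansion = 0.60,
                            p_upper_stomatal = NULL,
                            p_upper_senescence = 0.70) {
  hi_levels <- c("none", "moderate", "strong")
  aer_levels <- c("tolerant", "moderate", "sensitive")
  hi_pos_veg <- match.arg(hi_pos_veg, hi_levels)
  hi_pos_leaf <- match.arg(hi_pos_leaf, hi_levels)
  hi_neg_stomatal <- match.arg(hi_neg_stomatal, hi_levels)
  aeration <- match.arg(aeration, aer_levels)
  if (is.null(p_upper_stomatal)) {
    p_upper_stomatal <- c(none = 0.65, moderate = 0.50,
                          strong = 0.35)[[hi_neg_stomatal]]
  }
  structure(list(
    hi_pos_veg = hi_pos_veg,
    hi_pos_leaf = hi_pos_leaf,
    hi_neg_stomatal = hi_neg_stomatal,
    aeration = aeration,
    p_upper_flowering = as.numeric(p_upper_flowering),
    p_upper_expansion = as.numeric(p_upper_expansion),
    p_lower_expansion = as.numeric(p_lower_expansion),
    p_upper_stomatal = as.numeric(p_upper_stomatal),
    p_lower_stomatal = 1.0,
    p_upper_senescence = as.numeric(p_upper_senescence),
    p_lower_senescence = 1.0,
    aeration_margin = c(tolerant = 0.01, moderate = 0.03,
                        sensitive = 0.05)[[aeration]],
    hi_adjustment_caps = c(none = 0.0, moderate = 0.10, strong = 0.20)
  ), class = "stress_settings")
}

#' @export
default_stress_settings <- function() stress_settings()

.ideotype_registry <- function() {
  list(
    # Sugarcane baseline: the already-parameterized crop whose growth habit
    # most resembles hemp; starting point of the ideotyping procedure.
    sugarcane_baseline = crop_parameter_set(
      name = "sugarcane_baseline",
      t_base = 9.0, t_upper = 32.0,
      ccx = 0.95, cgc = 0.12548, cdc = 0.07615,
      zr_min = 0.30, zr_max = 1.80,
      d_emergence = 7L, d_max_root = 60L,
      d_flowering = NA, d_flowering_length = NA,
      d_hi_buildup = 20L, d_senescence = 330L, d_maturity = 365L,
      wp_normalized = 30, hi_ref = 0.35,
      plant_population = 140000,
      stress_settings = stress_settings(
        hi_pos_veg = "moderate", hi_pos_leaf = "moderate",
        hi_neg_stomatal = "moderate", aeration = "sensitive")
    ),
    hemp_grain = crop_parameter_set(
      name = "hemp_grain",
      t_base = 1.5, t_upper = 40.0,
      ccx = 0.90, cgc = 0.24917, cdc = 0.09615,
      zr_min = 0.30, zr_max = 2.00,
      d_emergence = 10L, d_max_root = 60L,
      d_flowering = 74L, d_flowering_length = 17L,
      d_hi_buildup = 15L, d_senescence = 105L, d_maturity = 140L,
      wp_normalized = 25, hi_ref = 0.23,
      plant_population = 140000,
      stress_settings = stress_settings(
        hi_pos_veg = "moderate", hi_pos_leaf = "moderate",
        hi_neg_stomatal = "strong", aeration = "sensitive",
        p_upper_flowering = 0.90)
    ),
    hemp_fibre = crop_parameter_set(
      name = "hemp_fibre",
      t_base = 1.5, t_upper = 40.0,
      ccx = 0.95, cgc = 0.11917, cdc = 0.09615,
      zr_min = 0.30, zr_max = 2.00,
      d_emergence = 10L, d_max_root = 60L,
      d_flowering = 72L, d_flowering_length = 17L,
      d_hi_buildup = 15L, d_senescence = 105L, d_maturity = 140L,
      wp_normalized = 18, hi_ref = 1.00,  # fibre yield = total biomass
      plant_population = 140000,
      stress_settings = stress_settings(
        hi_pos_veg = "moderate", hi_pos_leaf = "moderate",
        hi_neg_stomatal = "strong", aeration = "sensitive")
    )
  )
}

#' Built-in ideotypes
#'
#' Returns one of the three shipped crop parameter sets: the grain-hemp and
#' fibre-hemp ideotypes, or the sugarcane baseline they were derived from.
#'
#' @param name one of `"hemp_grain"`, `"hemp_fibre"`, `"sugarcane_baseline"`.
#' @return A `crop_params` object.
#' @examples
#' builtin_ideotype("hemp_grain")$wp_normalized  # 25 g m^-2
#' @export
builtin_ideotype <- function(name) {
  reg <- .ideotype_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg)) {
    stop("unknown ideotype '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(reg), collapse = ", "),
         call. = FALSE)
  }
  reg[[name]]
}

#' Validate a crop parameter set
#'
#' Checks every structural invariant and returns a character vector of
#' violation descriptions, empty when the set is valid. Each message names
#' the offending field(s) and the rule.
#'
#' @param params a `crop_params` object.
#' @return Character vector of violations (length 0 when valid).
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  add <- function(cond, msg) if (isTRUE(cond)) c(v, msg) else v

  v <- add(!(params$cc0 > 0), "cc0 must be > 0")
  v <- add(!(params$cc0 < params$ccx), "cc0 < ccx violated")
  v <- add(!(params$ccx <= 1), "ccx must be <= 1")
  v <- add(!(params$cgc > 0), "cgc must be > 0")
  v <- add(!(params$cdc > 0), "cdc must be > 0")
  v <- add(!(params$zr_min > 0), "zr_min must be > 0")
  v <- add(!(params$zr_min <= params$zr_max), "zr_min <= zr_max violated")
  v <- add(!(params$hi_ref > 0 && params$hi_ref <= 1),
           "hi_ref must be in (0, 1]")
  v <- add(!(params$wp_normalized > 0), "wp_normalized must be > 0")
  v <- add(!(params$t_base < params$t_upper), "t_base < t_upper violated")
  v <- add(!(params$d_emergence >= 0), "d_emergence must be >= 0")
  v <- add(!(params$d_senescence <= params$d_maturity),
           "d_senescence <= d_maturity violated")
  v <- add(!(params$d_max_root <= params$d_maturity),
           "d_max_root <= d_maturity violated")
  v <- add(!(params$d_hi_buildup > 0), "d_hi_buildup must be > 0")
  if (!is.na(params$d_flowering)) {
    v <- add(!(params$d_emergence < params$d_flowering),
             "d_emergence < d_flowering violated")
    v <- add(!(params$d_flowering < params$d_senescence),
             "d_flowering < d_senescence violated")
  }
  s <- params$stress_settings
  thr <- c(p_upper_flowering = s$p_upper_flowering,
           p_upper_expansion = s$p_upper_expansion,
           p_lower_expansion = s$p_lower_expansion,
           p_upper_stomatal = s$p_upper_stomatal,
           p_upper_senescence = s$p_upper_senescence)
  bad <- names(thr)[!is.na(thr) & (thr < 0 | thr > 1)]
  if (length(bad)) {
    v <- c(v, paste0("stress threshold(s) outside [0,1]: ",
                     paste(bad, collapse = ", ")))
  }
  v <- add(!(s$p_upper_expansion < s$p_lower_expansion),
           "p_upper_expansion < p_lower_expansion violated")
  v <- add(!(s$p_upper_stomatal < s$p_lower_stomatal),
           "p_upper_stomatal < p_lower_stomatal violated")
  v <- add(!(s$p_upper_senescence < s$p_lower_senescence),
           "p_upper_senescence < p_lower_senescence violated")
  v
}

.assert_valid_params <- function(params) {
  v <- validate_parameters(params)
  if (length(v)) {
    stop("invalid crop parameter set:\n  - ",
         paste(v, collapse = "\n  - "), call. = FALSE)
  }
  invisible(params)
}

# ---- crop file I/O ---------------------------------------------------------
# Flat key-value text format, one crop per file, `#` comments, keys carry a
# unit suffix. Categorical stress settings are stored as their level names.

.crop_file_keys <- c(
  name = "name",
  t_base = "t_base_degC", t_upper = "t_upper_degC",
  ccx = "ccx_frac", cgc = "cgc_per_day", cdc = "cdc_per_day",
  zr_min = "zr_min_m", zr_max = "zr_max_m",
  d_emergence = "d_emergence_das", d_max_root = "d_max_root_das",
  d_flowering = "d_flowering_das",
  d_flowering_length = "d_flowering_length_days",
  d_hi_buildup = "d_hi_buildup_days",
  d_senescence = "d_senescence_das", d_maturity = "d_maturity_das",
  wp_normalized = "wp_normalized_g_m2", hi_ref = "hi_ref_frac",
  plant_population = "plant_population_per_ha",
  seedling_cover = "seedling_cover_m2",
  hi_onset_offset = "hi_onset_offset_days"
)

.stress_file_keys <- c(
  hi_pos_veg = "stress_hi_pos_veg",
  hi_pos_leaf = "stress_hi_pos_leaf",
  hi_neg_stomatal = "stress_hi_neg_stomatal",
  aeration = "stress_aeration",
  p_upper_flowering = "stress_p_upper_flowering",
  p_upper_expansion = "stress_p_upper_expansion",
  p_lower_expansion = "stress_p_lower_expansion",
  p_upper_stomatal = "stress_p_upper_stomatal",
  p_upper_senescence = "stress_p_upper_senescence"
)

#' Write a crop parameter set to a key-value text file
#'
#' @param params a valid `crop_params` object.
#' @param path output file path.
#' @export
write_crop_parameters <- function(params, path) {
  .assert_valid_params(params)
  fmt <- function(x) {
    if (is.character(x)) x
    else if (length(x) == 0 || is.na(x)) "NA"
    else format(x, digits = 17, scientific = FALSE, trim = TRUE)
  }
  lines <- c("# ideocrop crop parameter file")
  for (f in names(.crop_file_keys)) {
    lines <- c(lines, paste(.crop_file_keys[[f]], "=", fmt(params[[f]])))
  }
  s <- params$stress_settings
  for (f in names(.stress_file_keys)) {
    lines <- c(lines, paste(.stress_file_keys[[f]], "=", fmt(s[[f]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a crop parameter set from a key-value text file
#'
#' Reads the format written by [write_crop_parameters()]; the writer/reader
#' pair round-trips any valid parameter set losslessly. Missing required
#' keys and invariant violations raise errors naming every problem found.
#'
#' @param path path to a crop parameter file.
#' @return A validated `crop_params` object.
#' @export
load_crop_parameters <- function(path) {
  if (!file.exists(path)) stop("crop file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) {
    stop("unparseable crop-file line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  names(vals) <- keys

  required <- c(.crop_file_keys, .stress_file_keys)
  # seedling_cover / hi_onset_offset / flowering keys are optional
  optional <- c("seedling_cover_m2", "hi_onset_offset_days",
                "d_flowering_das", "d_flowering_length_days",
                "stress_p_upper_flowering")
  missing <- setdiff(setdiff(unname(required), optional), keys)
  if (length(missing)) {
    stop("missing required crop-file key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(key, default = NA_real_) {
    if (!key %in% keys) return(default)
    x <- vals[[key]]
    if (identical(x, "NA")) return(NA_real_)
    out <- suppressWarnings(as.numeric(x))
    if (is.na(out)) stop("non-numeric value for key ", key, call. = FALSE)
    out
  }
  chr <- function(key, default = NA_character_) {
    if (!key %in% keys) default else vals[[key]]
  }
  ss <- stress_settings(
    hi_pos_veg = chr("stress_hi_pos_veg"),
    hi_pos_leaf = chr("stress_hi_pos_leaf"),
    hi_neg_stomatal = chr("stress_hi_neg_stomatal"),
    aeration = chr("stress_aeration"),
    p_upper_flowering = num("stress_p_upper_flowering"),
    p_upper_expansion = num("stress_p_upper_expansion"),
    p_lower_expansion = num("stress_p_lower_expansion"),
    p_upper_stomatal = num("stress_p_upper_stomatal"),
    p_upper_senescence = num("stress_p_upper_senescence")
  )
  p <- crop_parameter_set(
    name = chr("name"),
    t_base = num("t_base_degC"), t_upper = num("t_upper_degC"),
    ccx = num("ccx_frac"), cgc = num("cgc_per_day"), cdc = num("cdc_per_day"),
    zr_min = num("zr_min_m"), zr_max = num("zr_max_m"),
    d_emergence = num("d_emergence_das"),
    d_max_root = num("d_max_root_das"),
    d_flowering = num("d_flowering_das"),
    d_flowering_length = num("d_flowering_length_days"),
    d_hi_buildup = num("d_hi_buildup_days"),
    d_senescence = num("d_senescence_das"),
    d_maturity = num("d_maturity_das"),
    wp_normalized = num("wp_normalized_g_m2"),
    hi_ref = num("hi_ref_frac"),
    plant_population = num("plant_population_per_ha"),
    seedling_cover = num("seedling_cover_m2", 5e-4),
    hi_onset_offset = num("hi_onset_offset_days", 0),
    stress_settings = ss
  )
  .assert_valid_params(p)
  p
}

#' @export
print.crop_params <- function(x, ...) {
  cat("<crop_params> ", x$name, "\n", sep = "")
  cat(sprintf("  canopy: cc0 %.4f -> ccx %.2f  (cgc %.5f, cdc %.5f /d)\n",
              x$cc0, x$ccx, x$cgc, x$cdc))
  cat(sprintf("  roots: %.2f -> %.2f m by day %d\n",
              x$zr_min, x$zr_max, x$d_max_root))
  cat(sprintf("  calendar: emergence %d, flowering %s, senescence %d, maturity %d\n",
              x$d_emergence,
              if (is.na(x$d_flowering)) "-" else x$d_flowering,
              x$d_senescence, x$d_maturity))
  cat(sprintf("  WP* %.1f g m^-2, HI %.2f, %s plants/ha\n",
              x$wp_normalized, x$hi_ref,
              format(x$plant_population, big.mark = " ")))
  invisible(x)
}
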