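#' Generate synthetic observations from a known-truth simulation
#'
#' Runs the engine for `params` on seeded synthetic weather and turns the
#' outcome into an [observations()] table: final biomass and yield plus the
#' phenology landmarks, with optional seeded Gaussian observation noise
#' (truncated at zero, since all observed quantities are nonnegative).
#' With zero noise the observations equal the simulated values exactly,
#' which makes this the workhorse of parameter-recovery experiments.
#'
#' @param params a `crop_params` object (the "truth").
#' @param weather_seed seed for the synthetic weather series.
#' @param noise_sd named numeric vector of observation noise SDs:
#'   `biomass`, `yield` (t/ha) and `phenology_day` (days); missing names
#'   default to 0.
#' @param seed seed for the observation noise.
#' @param config synthetic-climate configuration.
#' @param soil,mgmt,control forwarded to [run_simulation()].
#' @param n_days length of the generated weather series.
#' @param phenology_labels which landmarks of [phenology_days()] to
#'   observe.
#' @return List with `obs` (an `observations` table), `truth` (the
#'   noise-free values), `result` (the underlying `simulation_result`) and
#'   `weather` (the series used).
#' @export
make_truth_observations <- function(params, weather_seed,
                                    noise_sd = c(biomass = 0, yield = 0,
                                                 phenology_day = 0),
                                    seed = 1L,
                                    config = default_climate_config(),
                                    soil = builtin_soil("clay_loam"),
                                    mgmt = management_config(),
                                    control = simulation_control(),
                                    n_days = 550L,
                                    phenology_labels = c("emergence",
                                                         "flowering",
                                                         "senescence",
                                                         "maturity")) {
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  sd_of <- function(v) if (v %in% names(noise_sd)) noise_sd[[v]] else 0

  weather <- generate_synthetic_weather(config, n_days = n_days,
                                        seed = weather_seed)
  result <- run_simulation(params, weather, soil, mgmt, control)
  ph <- phenology_days(params)
  phenology_labels <- phenology_labels[!is.na(ph[phenology_labels])]

  truth <- data.frame(
    variable = c("biomass", "yield", rep("phenology_day",
                                         length(phenology_labels))),
    label = c("final", "final", phenology_labels),
    value = c(result$finals$biomass, result$finals$yield,
              unname(ph[phenology_labels])),
    stringsAsFactors = FALSE)

  noisy <- .with_seed(seed, {
    sds <- vapply(truth$variable, sd_of, numeric(1))
    pmax(0, truth$value + stats::rnorm(nrow(truth), 0, sds))
  })
  obs <- truth
  obs$value <- noisy

  list(obs = observations(obs), truth = observations(truth),
       result = result, weather = weather)
}

#' Fixture bundles for regression pinning
#'
#' A fixture bundle names an ideotype, soil, synthetic-weather seed and
#' management, and carries a numeric digest of the resulting daily table so
#' that regenerating the bundle from its configuration can be checked for
#' bit-identical reproduction.
#'
#' @param ideotype a built-in ideotype name.
#' @param soil_name a built-in soil name.
#' @param weather_seed integer seed.
#' @param n_days weather length.
#' @return List of class `fixture_bundle` with the configuration, the
#'   `simulation_result` and `digest`.
#' @export
fixture_bundle <- function(ideotype = "hemp_grain",
                           soil_name = "clay_loam",
                           weather_seed = 101L, n_days = 550L) {
  params <- builtin_ideotype(ideotype)
  soil <- builtin_soil(soil_name)
  weather <- generate_synthetic_weather(n_days = n_days, seed = weather_seed)
  result <- run_simulation(params, weather, soil)
  structure(list(ideotype = ideotype, soil_name = soil_name,
                 weather_seed = weather_seed, n_days = n_days,
                 result = result,
                 digest = .result_digest(result)),
            class = "fixture_bundle")
}

# Order-sensitive numeric digest of a simulation's daily table; identical
# runs give identical digests.
.result_digest <- function(result) {
  num <- vapply(result$daily, is.numeric, TRUE)
  m <- as.matrix(result$daily[num])
  sum(m * rep(seq_len(ncol(m)), each = nrow(m)) +
        m^2 / (1 + col(m) + row(m)))
}

#' Regenerate the shipped plain-text fixtures
#'
#' Writes the three built-in crop files and the clay-loam soil file into
#' `dir` from code, so the packaged fixtures can be reproduced verbatim.
#'
#' @param dir output directory.
#' @export
regenerate_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("hemp_grain", "hemp_fibre", "sugarcane_baseline")) {
    write_crop_parameters(builtin_ideotype(nm),
                          file.path(dir, paste0(nm, ".crop")))
  }
  write_soil(builtin_soil("clay_loam"), file.path(dir, "clay_loam.soil"))
  invisible(dir)
}
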