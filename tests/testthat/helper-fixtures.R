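# Shared fixtures: seeded weather, management variants, and a cached
# unstressed grain-hemp run used by several files.

default_weather <- function(seed = 42L, n_days = 550L) {
  generate_synthetic_weather(n_days = n_days, seed = seed)
}

# Daily heavy irrigation keeps root-zone depletion at zero all season.
irrigated_mgmt <- function(planting = as.Date("2014-07-31"), mm = 30,
                           days = 250) {
  management_config(
    planting_date = planting,
    irrigation_schedule = data.frame(date = planting + seq_len(days),
                                     mm = mm))
}

unstressed_grain_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_simulation(builtin_ideotype("hemp_grain"),
                               default_weather(),
                               mgmt = irrigated_mgmt())
    }
    cache
  }
})

# A random but invariant-satisfying crop parameter set, for property tests.
random_valid_params <- function(seed) {
  set.seed(seed)
  d_em <- sample(3:20, 1)
  d_fl <- d_em + sample(20:80, 1)
  d_sen <- d_fl + sample(10:60, 1)
  d_mat <- d_sen + sample(5:60, 1)
  crop_parameter_set(
    name = paste0("random_", seed),
    t_base = runif(1, 0, 10), t_upper = runif(1, 25, 45),
    ccx = runif(1, 0.5, 0.99), cgc = runif(1, 0.08, 0.3),
    cdc = runif(1, 0.05, 0.15),
    zr_min = 0.3, zr_max = runif(1, 0.5, 2.5),
    d_emergence = d_em, d_max_root = min(d_mat, d_em + sample(20:80, 1)),
    d_flowering = d_fl, d_flowering_length = sample(5:25, 1),
    d_hi_buildup = sample(5:30, 1),
    d_senescence = d_sen, d_maturity = d_mat,
    wp_normalized = runif(1, 10, 35), hi_ref = runif(1, 0.1, 1),
    plant_population = 140000)
}
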