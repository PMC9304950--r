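# Small cohort builders shared across tests.

quick_config <- function(n_pairs = 200, n_waves = 2, ace = c(0.33, 0.07, 0.6),
                         rho_a = 0.95, rho_c = 0.9, rho_e = 0.41,
                         seed = 1, ...) {
  sim_config(n_mz_pairs = n_pairs, n_dz_pairs = n_pairs, n_waves = n_waves,
             measures = "y", ace = ace,
             corr_a = cs_corr(n_waves, rho_a),
             corr_c = cs_corr(n_waves, rho_c),
             corr_e = cs_corr(n_waves, rho_e),
             wave_shifts = rep(0, n_waves), sex_effect = 0,
             seed = seed, ...)
}

quick_cohort <- function(...) simulate_cohort(quick_config(...))

# compound-symmetric longitudinal sample of unrelated individuals
cs_sample <- function(n, waves, rho, seed = 1) {
  set.seed(seed)
  MASS::mvrnorm(n, rep(0, waves), cs_corr(waves, rho))
}
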