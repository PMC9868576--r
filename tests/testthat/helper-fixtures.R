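# Shared fixtures: small parameter vectors and simulated choice sets.

mh_params <- function(kappa = 0.05, s = 1, beta = 0.3) {
  param_vector("modified_hyperboloid", kappa = kappa, s = s, beta = beta)
}

# A compact indifference-free trial set spanning the default grid.
small_trials <- function() {
  grid <- expand.grid(delay_days = c(7, 90, 365),
                      r_del = c(10, 50))
  grid$r_imm <- grid$r_del * c(0.9, 0.5, 0.2)
  grid[, c("r_imm", "r_del", "delay_days")]
}

simulated_data <- function(params = mh_params(), seed = 11,
                           trials = generate_run_a()) {
  simulate_choices(agent_spec(params, seed), trials)
}

# Brute-force grid oracle: best negative log-likelihood over a regular
# 3-D parameter grid, independent of the optimiser.
grid_oracle_nll <- function(data, kappa_grid, s_grid, beta_grid) {
  best <- Inf
  for (k in kappa_grid) for (s in s_grid) for (b in beta_grid) {
    nll <- -log_likelihood(
      param_vector("modified_hyperboloid", kappa = k, s = s, beta = b),
      data)
    if (nll < best) best <- nll
  }
  best
}
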