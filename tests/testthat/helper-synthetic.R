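# Shared generators for the test suite.

# Small AR cohort config with a flexible number of waves/items.
tiny_config <- function(n = 200, T_ = 3, K = 6, beta = 0.7, tau = 0.6,
                        seed = 1, loadings = rep(1, K),
                        covariate_effects = list(),
                        outcome_coeffs = list(), mcar_rate = 0) {
  synthetic_config(
    n_households = n, n_waves = T_, n_items = K,
    wave_labels = as.character(seq_len(T_)),
    latent_init_mean = 0, latent_init_sd = 1,
    ar_intercepts = rep(0.2, T_ - 1),
    ar_slopes = rep(beta, T_ - 1),
    innovation_sds = rep(tau, T_ - 1),
    item_loadings = loadings,
    item_thresholds = lapply(seq_len(K), function(k)
      qnorm(0.2 + 0.6 * (k - 1) / max(K - 1, 1)) * sqrt(loadings[k]^2 + 1)),
    covariate_effects = covariate_effects,
    outcome_coeffs = outcome_coeffs,
    mcar_rate = mcar_rate,
    seed = seed)
}

# Random wealth matrix with named waves (no structure imposed).
random_wealth <- function(n = 50, T_ = 4, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * T_, sd = runif(1, 0.5, 2)), n, T_,
         dimnames = list(NULL, as.character(seq_len(T_))))
}

# Discretize a bivariate normal sample at given thresholds and return the
# contingency table: the independent route to a polychoric test case.
discretized_binormal_table <- function(n, rho, th_x, th_y, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  table(findInterval(x, th_x), findInterval(y, th_y))
}
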