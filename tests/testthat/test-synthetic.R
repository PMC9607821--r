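test_that("identical config and seed give bit-identical cohorts", {
  cfg <- tiny_config(n = 100, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$asset_panel$values, b$asset_panel$values)
  expect_identical(a$latent_wealth, b$latent_wealth)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$outcome, b$outcome)
})

test_that("changing the item count does not reshuffle covariates or latent wealth", {
  a <- simulate_cohort(tiny_config(n = 80, K = 4, seed = 9))
  b <- simulate_cohort(tiny_config(n = 80, K = 8, seed = 9))
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$latent_wealth, b$latent_wealth)
})

test_that("zero innovation sds give perfect canalization: conditionals identically zero", {
  cfg <- tiny_config(n = 150, T_ = 4, tau = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_true(all(abs(co$true_conditionals) < 1e-12))
  # downstream decomposition refuses the degenerate (collinear) history
  expect_error(fit_conditional(co$latent_wealth), "canalized")
  # with a single prior wave the residuals are numerically zero instead
  m2 <- fit_conditional(co$latent_wealth[, 1:2])
  expect_lt(max(abs(m2$conditional)), 1e-10)
  expect_lt(unexplained_share(m2, "2"), 1e-16)
})

test_that("zero AR slopes decouple later waves from the anchor", {
  cfg <- tiny_config(n = 10000, T_ = 3, beta = 0, tau = 1, seed = 11)
  co <- simulate_cohort(cfg)
  w <- co$latent_wealth
  expect_lt(abs(cor(w[, 1], w[, 2])), 3 / sqrt(10000))
  expect_lt(abs(cor(w[, 1], w[, 3])), 3 / sqrt(10000))
})

test_that("latent wealth matches closed-form AR moments at n = 10000", {
  beta <- 0.7; tau <- 0.6
  cfg <- tiny_config(n = 10000, T_ = 3, beta = beta, tau = tau, seed = 5)
  co <- simulate_cohort(cfg)
  w <- co$latent_wealth
  # wave 2: mean = 0.2 + beta * 0, var = beta^2 * 1 + tau^2
  expect_equal(mean(w[, 2]), 0.2, tolerance = 0.05)
  expect_equal(var(w[, 2]), beta^2 + tau^2, tolerance = 0.05)
  # wave 3 variance: beta^2 * var(w2) + tau^2
  expect_equal(var(w[, 3]), beta^2 * (beta^2 + tau^2) + tau^2,
               tolerance = 0.05)
  # innovations uncorrelated with earlier waves
  expect_lt(abs(cor(co$true_conditionals[, 2], w[, 1])), 3 / sqrt(10000))
  expect_lt(abs(cor(co$true_conditionals[, 2], w[, 2])), 3 / sqrt(10000))
})

test_that("the CLHNS-like default config matches the published cohort dimensions", {
  cfg <- clhns_like_config()
  expect_equal(cfg$n_households, 1581L)
  expect_equal(cfg$n_items, 30L)
  expect_equal(cfg$n_waves, 7L)
  expect_equal(cfg$wave_labels,
               c("1983", "1991", "1994", "1998", "2002", "2005", "2009"))
})

test_that("config validation rejects malformed inputs", {
  expect_error(synthetic_config(10, 3, 2,
                                ar_intercepts = 0, ar_slopes = 0,
                                innovation_sds = 0,
                                item_loadings = c(1, 1),
                                item_thresholds = list(0, 0)),
               "length n_waves - 1")
  expect_error(synthetic_config(10, 2, 1,
                                ar_intercepts = 0, ar_slopes = 0,
                                innovation_sds = -1,
                                item_loadings = 1, item_thresholds = list(0)),
               ">= 0")
  expect_error(synthetic_config(10, 2, 1,
                                ar_intercepts = 0, ar_slopes = 0,
                                innovation_sds = 1,
                                item_loadings = 1,
                                item_thresholds = list(c(1, 0))),
               "strictly increasing")
})

test_that("MCAR masking drops whole household-waves at the configured rate", {
  cfg <- tiny_config(n = 2000, T_ = 4, seed = 8, mcar_rate = 0.04)
  co <- simulate_cohort(cfg)
  v <- co$asset_panel$values
  miss_hw <- apply(v, c(1, 2), function(x) all(is.na(x)))
  part_hw <- apply(v, c(1, 2), function(x) any(is.na(x)) && !all(is.na(x)))
  expect_false(any(part_hw))
  expect_lt(abs(mean(miss_hw) - 0.04), 0.01)
})
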