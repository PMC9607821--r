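test_that("four-point worked example matches hand normal equations", {
  W <- cbind(`1` = c(0, 1, 2, 3), `2` = c(1, 1, 3, 3))
  m <- fit_conditional(W)
  b <- m$coefficients[["2"]]
  expect_equal(unname(b["(Intercept)"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(b["1"]), 0.8, tolerance = 1e-12)
  expect_equal(as.numeric(m$conditional), c(0.2, -0.6, 0.6, -0.2),
               tolerance = 1e-12)
  expect_equal(unexplained_share(m, "2"), 0.2, tolerance = 1e-12)
})

test_that("exact linear dependence on the past is the canalization limit", {
  w1 <- rnorm(50)
  W <- cbind(`1` = w1, `2` = 2 * w1)
  m <- fit_conditional(W)
  expect_lt(max(abs(m$conditional)), 1e-12)
  expect_lt(unexplained_share(m, "2"), 1e-20)
  # collinear *history* (two identical prior waves) must error
  W3 <- cbind(`1` = w1, `2` = w1, `3` = rnorm(50))
  expect_error(fit_conditional(W3), "canalized/collinear")
})

test_that("independent waves leave nearly all variance unexplained", {
  cfg <- tiny_config(n = 10000, T_ = 2, beta = 0, tau = 1, seed = 23)
  co <- simulate_cohort(cfg)
  m <- fit_conditional(co$latent_wealth)
  expect_lt(abs(m$coefficients[["2"]][["1"]]), 0.03)
  expect_gt(unexplained_share(m, "2"), 0.97)
})

test_that("decomposition is exact and residuals orthogonal to all prior waves", {
  for (seed in 1:5) {
    W <- random_wealth(120, 5, seed)
    m <- fit_conditional(W)
    for (j in seq_len(ncol(m$conditional))) {
      t <- j + 1L
      c_t <- m$conditional[, j]
      expect_lt(abs(mean(c_t)), 1e-8)
      expect_equal(W[, t], m$fitted[, j] + c_t, tolerance = 1e-12)
      for (s in seq_len(t - 1L))
        expect_lt(abs(cor(c_t, W[, s])), 1e-8)
    }
  }
})

test_that("two-wave variance identity holds to numerical precision", {
  W <- random_wealth(300, 2, seed = 31)
  m <- fit_conditional(W)
  b1 <- m$coefficients[["2"]][["1"]]
  expect_lt(abs(var(W[, 2]) - (b1^2 * var(W[, 1]) + var(m$conditional[, 1]))),
            1e-8)
})

test_that("fitted residuals track the true innovations on synthetic data", {
  cfg <- tiny_config(n = 5000, T_ = 3, beta = 0.7, tau = 0.6, seed = 29)
  co <- simulate_cohort(cfg)
  m <- fit_conditional(co$latent_wealth)
  expect_gt(cor(m$conditional[, 1], co$true_conditionals[, 1]), 0.95)
  expect_gt(cor(m$conditional[, 2], co$true_conditionals[, 2]), 0.95)
})

test_that("stage-1 covariate adjustment orthogonalizes against covariates", {
  set.seed(37)
  n <- 2000
  w1 <- rnorm(n)
  x2 <- 0.5 * w1 + rnorm(n)        # covariate fed back from early wealth
  w2 <- 0.3 + 0.7 * w1 + 0.4 * x2 + rnorm(n, sd = 0.6)
  W <- cbind(`1` = w1, `2` = w2)
  X <- data.frame(x2 = x2)
  plain <- fit_conditional(W)
  adj <- fit_conditional_adjusted(W, X)
  expect_lt(abs(cor(adj$conditional[, 1], x2)), 1e-8)
  expect_lt(abs(cor(adj$conditional[, 1], w1)), 1e-8)
  expect_lte(var(adj$conditional[, 1]), var(plain$conditional[, 1]))
  expect_gt(var(plain$conditional[, 1]) - var(adj$conditional[, 1]), 0.01)
  # a covariate orthogonal to both waves leaves residuals exactly unchanged
  xo <- residuals(lm(rnorm(n) ~ w1 + w2))
  adj2 <- fit_conditional_adjusted(W, data.frame(xo = xo))
  expect_equal(adj2$conditional[, 1], plain$conditional[, 1],
               tolerance = 1e-10)
})

test_that("covariates collinear with prior wealth are dropped with a warning", {
  W <- random_wealth(100, 2, seed = 41)
  X <- data.frame(dup = 2 * W[, 1] + 1)
  expect_warning(m <- fit_conditional_adjusted(W, X), "collinear")
  expect_length(m$covariates_used[["2"]], 0)
})

test_that("canalization diagnostics flag monotone intervals only", {
  w1 <- rnorm(200)
  W <- cbind(`1` = w1, `2` = w1^3 + 5)   # monotone, nonlinear
  d <- canalization_diagnostics(W, threshold = 0.9)
  expect_equal(d$spearman[1], 1)
  expect_true(d$flagged[1])
  Wi <- random_wealth(200, 2, seed = 43)
  di <- canalization_diagnostics(Wi, threshold = 0.9)
  expect_false(di$flagged[1])
  expect_lt(abs(di$spearman[1]), 0.2)
})

test_that("AR process calibrated to a target rank correlation reports it", {
  # beta/tau chosen so corr(w1, w2) ~ 0.7: beta^2/(beta^2 + tau^2) = 0.49
  beta <- 0.7
  tau <- beta * sqrt(1 / 0.49 - 1)
  cfg <- tiny_config(n = 20000, T_ = 2, beta = beta, tau = tau, seed = 47)
  co <- simulate_cohort(cfg)
  d <- canalization_diagnostics(co$latent_wealth)
  # for a bivariate normal, Spearman's rho = 6/pi * asin(r/2); with Pearson
  # r = 0.7 the rank correlation target is ~0.683
  expect_lt(abs(d$spearman[1] - 6 / pi * asin(0.7 / 2)), 0.05)
})
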