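test_that("adjustment set contains anchor, conditionals and covariates only", {
  W <- random_wealth(60, 3, seed = 1)
  m <- fit_conditional(W)
  expect_equal(build_adjustment_set(m, c("schooling", "sex")),
               c("w_1", "c_2", "c_3", "schooling", "sex"))
  expect_equal(build_adjustment_set(m, target_wave = "2"), c("w_1", "c_2"))
  expect_error(build_adjustment_set(m, c("schooling", "w_2")),
               "not for any other raw wealth measure")
  expect_error(build_adjustment_set(m, target_wave = "1"), ">= 2")
})

test_that("noiseless outcomes are identified exactly in both parameterizations", {
  set.seed(53)
  n <- 200
  w1 <- rnorm(n)
  w2 <- 0.5 + 0.8 * w1 + rnorm(n, sd = 0.7)
  W <- cbind(`1` = w1, `2` = w2)
  m <- fit_conditional(W)
  y <- 1 + 0.4 * w1 + 0.36 * m$conditional[, 1]
  fc <- fit_outcome_conditional(y, W, model = m)
  est <- setNames(fc$coefficients$estimate, fc$coefficients$term)
  expect_equal(unname(est["w_1"]), 0.4, tolerance = 1e-10)
  expect_equal(unname(est["c_2"]), 0.36, tolerance = 1e-10)
  expect_lt(max(fc$coefficients$se), 1e-10)
})

test_that("fixed-effects and conditional fits are reparameterizations of each other", {
  for (seed in 1:10) {
    set.seed(seed)
    T_ <- sample(2:5, 1)
    n <- 150 + 20 * seed
    W <- random_wealth(n, T_, seed + 100)
    X <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    y <- rnorm(n) + W %*% runif(T_, -0.5, 0.5) + 0.3 * X$x1
    m <- fit_conditional(W)
    ff <- fit_outcome_fixed(y, W, X)
    fc <- fit_outcome_conditional(y, W, model = m, X = X)
    eq <- check_equivalence(ff, fc, m)
    expect_lt(eq$latest_coef_diff, 1e-8)
    expect_lt(eq$anchor_mapping_diff, 1e-8)
    expect_lt(eq$fitted_diff, 1e-10)
    expect_true(eq$pass)
  }
})

test_that("two-wave anchor mapping equals a1 + a2 * b1 explicitly", {
  W <- random_wealth(250, 2, seed = 7)
  y <- 2 + 0.5 * W[, 1] - 0.3 * W[, 2] + rnorm(250)
  m <- fit_conditional(W)
  ff <- fit_outcome_fixed(y, W)
  fc <- fit_outcome_conditional(y, W, model = m)
  a <- setNames(ff$coefficients$estimate, ff$coefficients$term)
  ap <- setNames(fc$coefficients$estimate, fc$coefficients$term)
  b1 <- m$coefficients[["2"]][["1"]]
  expect_equal(unname(ap["w_1"]), unname(a["w_1"] + a["w_2"] * b1),
               tolerance = 1e-8)
  expect_equal(unname(ap["c_2"]), unname(a["w_2"]), tolerance = 1e-10)
})

test_that("including a raw wave and its conditional together is rank-deficient", {
  W <- random_wealth(80, 2, seed = 11)
  m <- fit_conditional(W)
  y <- rnorm(80)
  X <- data.frame(c2 = m$conditional[, 1])
  expect_error(fit_outcome_fixed(y, W, X), "rank-deficient")
})

test_that("null outcomes yield near-nominal false-positive rates", {
  hits <- 0L
  reps <- 60L
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    W <- random_wealth(400, 3, seed = 2000 + r)
    y <- rnorm(400)
    fc <- fit_outcome_conditional(y, W)
    z <- abs(fc$coefficients$estimate / fc$coefficients$se)[-1]
    hits <- hits + sum(z > 1.96)
  }
  rate <- hits / (reps * 3)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("predictors of conditional wealth recover the generating effect", {
  cfg <- tiny_config(
    n = 4000, T_ = 3, K = 4, seed = 59,
    covariate_effects = list(maternal_schooling_on_first_innovation = 0.04))
  co <- simulate_cohort(cfg)
  m <- fit_conditional(co$latent_wealth)
  pf <- predict_conditional(m, co$covariates, "2",
                            covariates = "maternal_schooling")
  est <- pf$coefficients[pf$coefficients$term == "maternal_schooling", ]
  expect_lt(abs(est$estimate - 0.04), 3 * est$se)
  # covariates independent of the innovations predict nothing
  pf3 <- predict_conditional(m, co$covariates, "3",
                             covariates = c("maternal_age", "birth_order"))
  z <- abs(pf3$coefficients$estimate / pf3$coefficients$se)[-1]
  expect_true(all(z < 4))
  expect_error(predict_conditional(m, co$covariates, "2",
                                   covariates = c("w_1", "maternal_age")),
               "anchor")
})

test_that("stratified fits split cleanly and recover group-specific effects", {
  # identical groups give identical coefficients
  W <- random_wealth(120, 2, seed = 61)
  y <- 1 + 0.5 * W[, 1] + 0.2 * W[, 2] + rnorm(120, sd = 0.1)
  Wd <- rbind(W, W); yd <- c(y, y)
  g <- rep(c("a", "b"), each = 120)
  m <- fit_conditional(Wd)
  sf <- stratified_fit(yd, Wd, model = m, group = g)
  expect_equal(sf$a$coefficients$estimate, sf$b$coefficients$estimate,
               tolerance = 1e-10)
  expect_error(stratified_fit(yd, Wd, model = m,
                              group = c(rep("a", 238), "b", "b")),
               "too small")
  # sex-specific conditional effect (0.5 vs 0) recovered per stratum
  set.seed(67)
  n <- 3000
  w1 <- rnorm(n); w2 <- 0.6 * w1 + rnorm(n, sd = 0.8)
  Ws <- cbind(`1` = w1, `2` = w2)
  ms <- fit_conditional(Ws)
  sex <- rep(c("f", "m"), length.out = n)
  a2 <- ifelse(sex == "m", 0.5, 0)
  ys <- 0.3 * w1 + a2 * ms$conditional[, 1] + rnorm(n, sd = 0.5)
  sfs <- stratified_fit(ys, Ws, model = ms, group = sex)
  em <- subset(sfs$m$coefficients, term == "c_2")
  ef <- subset(sfs$f$coefficients, term == "c_2")
  expect_lt(abs(em$estimate - 0.5), 3 * em$se)
  expect_lt(abs(ef$estimate - 0.0), 3 * ef$se)
})

test_that("bootstrap and robust SEs are in the same ballpark as classical", {
  set.seed(71)
  W <- random_wealth(300, 2, seed = 73)
  y <- 0.4 * W[, 1] + 0.3 * W[, 2] + rnorm(300)
  f0 <- fit_outcome_conditional(y, W)
  fb <- fit_outcome_conditional(y, W, bootstrap = 200, seed = 5)
  fr <- fit_outcome_conditional(y, W, robust = TRUE)
  expect_equal(fb$coefficients$estimate, f0$coefficients$estimate)
  expect_lt(max(abs(fb$coefficients$se / f0$coefficients$se - 1)), 0.35)
  expect_lt(max(abs(fr$coefficients$se / f0$coefficients$se - 1)), 0.35)
  expect_match(fb$se_type, "bootstrap")
})
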