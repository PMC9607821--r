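test_that("prevalence filter drops rare and constant items with reasons", {
  co <- simulate_cohort(tiny_config(n = 300, T_ = 2, K = 4, seed = 2))
  panel <- co$asset_panel
  # make item 4 very rare and item 3 constant in the pooled data
  v <- panel$values
  v[, , 4] <- 0L
  v[1:3, 1, 4] <- 1L           # ~0.5% prevalence
  v[, , 3] <- 1L
  panel2 <- asset_panel(v, panel$n_levels)
  flt <- filter_items(panel2, min_prevalence = 0.02)
  expect_setequal(flt$report$item[flt$report$dropped], c("item03", "item04"))
  expect_match(flt$report$reason[flt$report$item == "item03"], "constant")
  expect_match(flt$report$reason[flt$report$item == "item04"], "prevalence")
  # min_prevalence = 0 keeps everything except the constant item
  flt0 <- filter_items(panel2, min_prevalence = 0)
  expect_setequal(flt0$report$item[flt0$report$dropped], "item03")
  expect_error(filter_items(panel2, 0.6), "0, 0.5")
})

test_that("index build recovers the measurement loadings and standardizes scores", {
  loadings <- seq(0.5, 1.6, length.out = 30)
  cfg <- tiny_config(n = 5000, T_ = 3, K = 30, seed = 21,
                     loadings = loadings)
  co <- simulate_cohort(cfg)
  idx <- build_harmonized_index(co$asset_panel, min_prevalence = 0.01)
  expect_true(all(idx$loadings > 0))
  expect_gt(cor(idx$loadings, loadings, method = "spearman"), 0.9)
  W <- score_households(idx, co$asset_panel)
  pooled <- as.numeric(W)
  expect_lt(abs(mean(pooled)), 1e-8)
  expect_lt(abs(var(pooled) - 1), 1e-8)
  expect_gt(cor(pooled, as.numeric(co$latent_wealth)), 0.9)
})

test_that("index construction is deterministic and orientation-stable", {
  co <- simulate_cohort(tiny_config(n = 400, T_ = 2, K = 5, seed = 6))
  i1 <- build_harmonized_index(co$asset_panel)
  i2 <- build_harmonized_index(co$asset_panel)
  expect_identical(i1$loadings, i2$loadings)
  # orientation: index increases with asset ownership
  expect_gt(cor(as.numeric(score_households(i1, co$asset_panel)),
                rowSums(matrix(co$asset_panel$values,
                               ncol = dim(co$asset_panel)[3]))), 0)
})

test_that("scores are monotone in item levels under positive loadings", {
  co <- simulate_cohort(tiny_config(n = 300, T_ = 2, K = 6, seed = 13))
  idx <- build_harmonized_index(co$asset_panel)
  v <- co$asset_panel$values
  v[1, , ] <- 0L
  top <- rep(co$asset_panel$n_levels - 1L, each = 1)
  for (k in seq_along(top)) v[2, , k] <- top[k]
  W <- score_households(idx, asset_panel(v, co$asset_panel$n_levels))
  expect_true(all(W[2, ] > W[1, ]))
})

test_that("scoring rejects unseen level codes and missing items", {
  co <- simulate_cohort(tiny_config(n = 100, T_ = 2, K = 4, seed = 3))
  idx <- build_harmonized_index(co$asset_panel)
  v <- co$asset_panel$values
  v[1, 1, 1] <- max(v[, , 1], na.rm = TRUE) + 5L
  bumped <- asset_panel(v)
  expect_error(score_households(idx, bumped), "unseen")
  sub <- asset_panel(co$asset_panel$values[, , 1:3, drop = FALSE],
                     co$asset_panel$n_levels[1:3])
  expect_error(score_households(idx, sub), "lacks index item")
})

test_that("within-wave rankings agree with a cross-sectional index", {
  cfg <- tiny_config(n = 1500, T_ = 3, K = 8, seed = 17)
  co <- simulate_cohort(cfg)
  idx_all <- build_harmonized_index(co$asset_panel)
  W_all <- score_households(idx_all, co$asset_panel)
  one <- panel_waves(co$asset_panel, "2")
  idx_one <- build_harmonized_index(one)
  W_one <- score_households(idx_one, one)
  expect_gt(cor(W_all[, "2"], W_one[, "2"], method = "spearman"), 0.9)
})
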