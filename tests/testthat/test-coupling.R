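world <- small_world(n_nodes = 14, n_time = 80)
preds <- build_predictors(world$geometry, world$sc)

test_that("node_design drops the diagonal and fixes column order", {
  x <- node_design(preds, 2)
  expect_equal(dim(x), c(13, 3))
  expect_identical(colnames(x), c("dist", "spl", "cmc"))
  expect_equal(x[, "dist"], preds$dist[2, -2])
  expect_error(node_design(preds, 0), "index")
  expect_error(node_design(preds, 15), "index")
})

test_that("fit_ols recovers exact linear responses", {
  x <- node_design(preds, 1)
  y <- 0.3 - 2 * x[, 1] + 0.5 * x[, 2] + 4 * x[, 3]
  fit <- fit_ols(x, y)
  expect_equal(unname(fit$beta), c(0.3, -2, 0.5, 4), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-8)
  expect_equal(fit$n_obs, 13)
  expect_equal(fit$n_pred, 3)
})

test_that("fit_ols adjusted R2 follows its defining identity", {
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- x[, 1] + rnorm(40)
  fit <- fit_ols(x, y)
  expect_equal(fit$adj_r2,
               1 - (1 - fit$r2) * (fit$n_obs - 1) /
                 (fit$n_obs - fit$n_pred - 1), tolerance = 1e-12)
  expect_lte(fit$adj_r2, fit$r2)
})

test_that("fit_ols errors on degenerate inputs", {
  x <- matrix(rnorm(20 * 3), 20, 3)
  expect_error(fit_ols(x, rep(2, 20)), "variance")
  expect_error(fit_ols(cbind(x, x[, 1]), rnorm(20)), "collinear")
  expect_error(fit_ols(x[1:4, ], rnorm(4)), "too few")
})

test_that("adjusted R2 is unbiased under the null", {
  set.seed(99)
  x <- matrix(rnorm(99 * 3), 99, 3)
  vals <- replicate(1000, fit_ols(x, rnorm(99))$adj_r2)
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("dynamic_coupling hits 1 on constructed linear frames", {
  ets <- array(rnorm(14 * 14 * 6, sd = 0.1), dim = c(14, 14, 6))
  for (t in 1:6) ets[, , t] <- (ets[, , t] + t(ets[, , t])) / 2
  x <- node_design(preds, 3)
  ets[3, -3, 2] <- 1 + 2 * x[, 1] - x[, 2] + 0.5 * x[, 3]
  ets[-3, 3, 2] <- ets[3, -3, 2]
  cm <- dynamic_coupling(preds, ets)
  expect_equal(dim(cm), c(14, 6))
  expect_equal(cm[3, 2], 1, tolerance = 1e-8)
})

test_that("dynamic_coupling is equivariant under node permutation", {
  w <- small_world(n_nodes = 10, n_time = 50)
  p <- build_predictors(w$geometry, w$sc)
  ets <- edge_time_series(zscore_activity(w$activity))
  cm <- dynamic_coupling(p, ets)
  perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  geom_p <- w$geometry[perm, ]
  p_p <- build_predictors(geom_p, w$sc[perm, perm])
  cm_p <- dynamic_coupling(p_p, ets[perm, perm, ])
  expect_equal(cm_p, cm[perm, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("dynamic_coupling flags degenerate frames as NA and counts them", {
  ets <- edge_time_series(zscore_activity(world$activity))
  ets[5, -5, 3] <- 0.7
  ets[-5, 5, 3] <- 0.7
  cm <- dynamic_coupling(preds, ets)
  expect_true(is.na(cm[5, 3]))
  expect_gte(attr(cm, "n_degenerate"), 1)
})

test_that("dynamic_coupling per-frame values match fit_ols one frame at a time", {
  ets <- edge_time_series(zscore_activity(world$activity))
  cm <- dynamic_coupling(preds, ets)
  for (i in c(1, 7)) for (t in c(2, 40)) {
    expect_equal(cm[i, t],
                 fit_ols(node_design(preds, i), ets[i, -i, t])$adj_r2,
                 tolerance = 1e-10)
  }
})

test_that("static_coupling: exact linear FC rows give 1; shape is right", {
  fc <- static_fc(world$activity)
  s <- static_coupling(preds, fc)
  expect_length(s, 14)
  fc2 <- fc
  x <- node_design(preds, 4)
  fc2[4, -4] <- 0.1 + x[, 1] - 2 * x[, 2] + x[, 3]
  fc2[-4, 4] <- fc2[4, -4]
  expect_equal(static_coupling(preds, fc2)[4], 1, tolerance = 1e-8)
})

test_that("mean-over-time of dynamic coupling differs from static coupling", {
  # R2 is nonlinear: applying the model to the mean tensor (static FC) is
  # not the same as averaging per-frame R2
  ets <- edge_time_series(zscore_activity(world$activity))
  cm <- dynamic_coupling(preds, ets)
  s <- static_coupling(preds, static_fc(world$activity))
  expect_gt(max(abs(rowMeans(cm, na.rm = TRUE) - s)), 1e-3)
})

test_that("spearman_rank_coupling: monotone, reversed, and midrank ties", {
  sc <- matrix(0, 4, 4)
  sc[1, 2:4] <- c(1, 2, 3); sc[2:4, 1] <- c(1, 2, 3)
  sc[2, 3] <- sc[3, 2] <- 1; sc[2, 4] <- sc[4, 2] <- 2; sc[3, 4] <- sc[4, 3] <- 5
  fc <- matrix(0.5, 4, 4); diag(fc) <- 1
  fc[1, 2:4] <- c(0.1, 0.2, 0.3); fc[2:4, 1] <- c(0.1, 0.2, 0.3)
  expect_equal(spearman_rank_coupling(sc, fc)[1], 1)
  fc[1, 2:4] <- c(0.3, 0.2, 0.1); fc[2:4, 1] <- c(0.3, 0.2, 0.1)
  expect_equal(spearman_rank_coupling(sc, fc)[1], -1)
  # midranks: sc (1,1,2) vs fc (5,5,9) is a perfect monotone relation
  sc[1, 2:4] <- c(1, 1, 2); sc[2:4, 1] <- c(1, 1, 2)
  fc[1, 2:4] <- c(5, 5, 9); fc[2:4, 1] <- c(5, 5, 9)
  expect_equal(spearman_rank_coupling(sc, fc)[1], 1)
})

test_that("spearman_rank_coupling warns and NA-fills sparse nodes", {
  sc <- matrix(0, 5, 5)
  sc[1, 2] <- sc[2, 1] <- 1
  sc[3, 4] <- sc[4, 3] <- 1; sc[3, 5] <- sc[5, 3] <- 2; sc[4, 5] <- sc[5, 4] <- 1
  sc[1, 3] <- sc[3, 1] <- 1; sc[1, 4] <- sc[4, 1] <- 2
  fc <- static_fc(matrix(rnorm(5 * 30), 5, 30))
  expect_warning(out <- spearman_rank_coupling(sc, fc), "< 3")
  expect_true(is.na(out[2]))
  expect_false(is.na(out[1]))
})

test_that("dominance analysis conserves full-model R2 and spots null predictors", {
  set.seed(8)
  # orthogonal informative predictors + pure-noise third column
  x1 <- rep(c(-1, 1), each = 50)
  x2 <- rep(c(-1, 1), times = 50)
  x3 <- rnorm(100)
  y <- 2 * x1 + 1 * x2 + rnorm(100, sd = 0.3)
  dom <- dominance_analysis(cbind(a = x1, b = x2, c = x3), y)
  expect_equal(sum(dom), attr(dom, "full_r2"), tolerance = 1e-10)
  expect_lt(dom["c"], 0.01)
  marg_a <- summary(lm(y ~ x1))$r.squared
  marg_b <- summary(lm(y ~ x2))$r.squared
  expect_equal(unname(dom["a"]), marg_a, tolerance = 0.02)
  expect_equal(unname(dom["b"]), marg_b, tolerance = 0.02)
})

test_that("dominance conservation holds on correlated designs too", {
  set.seed(12)
  for (i in 1:10) {
    x <- matrix(rnorm(60 * 3), 60, 3)
    x[, 2] <- x[, 1] + 0.5 * x[, 2]           # induce collinearity
    y <- x %*% c(1, -1, 0.5) + rnorm(60)
    dom <- dominance_analysis(x, y)
    expect_equal(sum(dom), attr(dom, "full_r2"), tolerance = 1e-10)
    expect_true(all(dom >= -1e-12))
  }
})

test_that("dominance of pure-noise responses is small and nonnegative", {
  set.seed(21)
  x <- matrix(rnorm(99 * 3), 99, 3)
  doms <- replicate(200, dominance_analysis(x, rnorm(99)))
  expect_true(all(doms >= 0))
  expect_lt(mean(doms), 0.02)
})
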