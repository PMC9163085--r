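test_that("coefficient_of_variation: worked examples and scale invariance", {
  cm <- rbind(c(1, 1, 1), c(2, 4, 3))
  cv <- coefficient_of_variation(cm)
  expect_equal(cv[1], 0)
  expect_equal(cv[2], sd(c(2, 4, 3)) / 3)
  # spec-style two-point convention check via a 3-frame series
  expect_equal(coefficient_of_variation(rbind(c(2, 4, 3)))[1],
               sd(c(2, 4, 3)) / mean(c(2, 4, 3)))
  # scaling by c > 0 leaves cv unchanged
  expect_equal(coefficient_of_variation(cm * 7)[2], cv[2])
})

test_that("coefficient_of_variation handles missing frames and zero means", {
  cm <- rbind(c(0.2, NA, 0.4, 0.3, NA), c(-1, 1, 0, 1, -1))
  expect_warning(cv <- coefficient_of_variation(cm), "near-zero")
  expect_equal(cv[1], sd(c(0.2, 0.4, 0.3)) / 0.3)
  expect_true(is.na(cv[2]))
})

test_that("dynamic_vs_static reproduces the worked micro-examples", {
  out <- dynamic_vs_static(rbind(c(0.1, 0.3, 0.5)), 0.2)
  expect_equal(out$prob_greater, 2 / 3)
  expect_equal(out$bias, 0.1)
  out2 <- dynamic_vs_static(rbind(0:4), 2)
  expect_equal(out2$variance, 3.36 - 0.64)
  # constant dynamic series equal to static: all three zero
  out3 <- dynamic_vs_static(rbind(rep(0.4, 10)), 0.4)
  expect_equal(unlist(out3[, 2:4]), c(prob_greater = 0, bias = 0,
                                      variance = 0))
})

test_that("dynamic_vs_static invariances: strict ties, translation", {
  # exact ties count as not-larger
  out <- dynamic_vs_static(rbind(c(0.2, 0.2, 0.5)), 0.2)
  expect_equal(out$prob_greater, 1 / 3)
  # percentile variance is translation-invariant
  x <- runif(50)
  v1 <- dynamic_vs_static(rbind(x), 0.5)$variance
  v2 <- dynamic_vs_static(rbind(x + 3), 0.5)$variance
  expect_equal(v1, v2)
})

test_that("coupling_similarity: identical, negated and independent series", {
  set.seed(4)
  base <- rnorm(1000)
  cm <- rbind(base, base, -base, rnorm(1000))
  sim <- coupling_similarity(cm)
  expect_equal(sim[1, 2], 1)
  expect_equal(sim[1, 3], -1)
  expect_lt(abs(sim[1, 4]), 0.1)
  expect_equal(diag(sim), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sim, t(sim))
  # averaging across two identical subjects changes nothing
  sim2 <- coupling_similarity(list(cm, cm))
  expect_equal(sim2, sim)
  expect_warning(coupling_similarity(rbind(rep(1, 10), rnorm(10))),
                 "constant")
})

test_that("connectivity_distance averages over structural neighbors", {
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- sc[2, 1] <- 1
  sc[1, 3] <- sc[3, 1] <- 5
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 2
  d[1, 3] <- d[3, 1] <- 4
  d[2, 3] <- d[3, 2] <- 6
  expect_equal(connectivity_distance(sc, d)[1], 3)
  # weighted variant pulls toward the strong connection
  expect_equal(connectivity_distance(sc, d, weighted = TRUE)[1],
               (1 * 2 + 5 * 4) / 6)
  # removing the longest connection strictly decreases the mean
  sc2 <- sc
  sc2[1, 3] <- sc2[3, 1] <- 0
  expect_lt(connectivity_distance(sc2, d)[1],
            connectivity_distance(sc, d)[1])
  # fully connected: row-mean excluding self
  scf <- matrix(1, 3, 3); diag(scf) <- 0
  expect_equal(connectivity_distance(scf, d), rowSums(d) / 2)
})

test_that("annotate_summary: group means and equal-count gradient bins", {
  geom <- gen_geometry(20, seed = 3)
  ann <- gen_annotations(geom, n_networks = 3, seed = 3)
  const <- rep(0.7, 20)
  out <- annotate_summary(const, ann, "network")
  expect_true(all(out$mean == 0.7))
  expect_equal(sum(out$n), 20)
  bins <- annotate_summary(seq_len(20), ann, "gradient_bins", n_bins = 10)
  expect_true(all(bins$n == 2))
  # bin means of the gradient itself are nondecreasing
  gbins <- annotate_summary(ann$gradient, ann, "gradient_bins", n_bins = 10)
  expect_true(all(diff(gbins$mean[order(gbins$group)]) >= 0))
  expect_error(annotate_summary(const, ann, "nonsense"))
})

test_that("gradient binning distributes remainders to the lowest bins", {
  geom <- gen_geometry(14, seed = 5)
  ann <- gen_annotations(geom, n_networks = 2, seed = 5)
  out <- annotate_summary(rnorm(14), ann, "gradient_bins", n_bins = 4)
  expect_equal(out$n[order(out$group)], c(4, 4, 3, 3))
})

test_that("group_similarity_contrast: pooled t-test mechanics", {
  # hand-computed pooled t for {1,2,3} vs {4,5,6}: t = -3.674, df = 4
  sim <- diag(4) * 0 + 0
  sim[1, 2] <- sim[2, 1] <- 1
  sim[1, 3] <- sim[3, 1] <- 2
  sim[1, 4] <- sim[4, 1] <- 3
  sim[2, 3] <- sim[3, 2] <- 4
  sim[2, 4] <- sim[4, 2] <- 5
  sim[3, 4] <- sim[4, 3] <- 6
  diag(sim) <- 1
  grouping <- matrix(0, 4, 4)
  grouping[1, 2] <- grouping[2, 1] <- 1
  grouping[1, 3] <- grouping[3, 1] <- 1
  grouping[1, 4] <- grouping[4, 1] <- 1
  out <- group_similarity_contrast(sim, grouping)
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  expect_equal(out$df, 4)
  expect_equal(out$n1 + out$n2, 4 * 3 / 2)
  # identical distributions: t = 0, p = 1
  sim2 <- matrix(0.5, 4, 4); diag(sim2) <- 1
  expect_warning(out2b <- group_similarity_contrast(sim2, grouping),
                 "variance")
  expect_equal(out2b$t, 0)
  expect_equal(out2b$p, 1)
})

test_that("group_similarity_contrast flags degenerate shifted groups", {
  sim <- matrix(0, 4, 4)
  sim[1, 2] <- sim[2, 1] <- 1   # group 1 constant at 1
  sim[1, 3] <- sim[3, 1] <- 1
  diag(sim) <- 1                # others constant at 0
  grouping <- matrix(0, 4, 4)
  grouping[1, 2] <- grouping[2, 1] <- 1
  grouping[1, 3] <- grouping[3, 1] <- 1
  expect_warning(out <- group_similarity_contrast(sim, grouping),
                 "undefined")
  expect_true(is.infinite(out$t))
})

test_that("same-network grouping uses upper-triangle pair bookkeeping", {
  labels <- c("a", "a", "b", "b", "b")
  sim <- matrix(rnorm(25), 5, 5)
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  out <- group_similarity_contrast(sim, labels)
  expect_equal(out$n1, 1 + 3)   # one a-a pair, three b-b pairs
  expect_equal(out$n1 + out$n2, 10)
})
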