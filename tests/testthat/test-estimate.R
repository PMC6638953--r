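test_that("Blom normal scores match the closed form and are rank-invariant", {
  m <- cbind(A = c(1, 2, 3))
  z <- normal_scores(as_cohort(m, levels = 0))
  expect_equal(unname(z[, 1]),
               qnorm((c(1, 2, 3) - 3 / 8) / (3 + 1 / 4)),
               tolerance = 1e-12)
  expect_equal(unname(z[2, 1]), 0)
  # strictly monotone transforms leave the scores unchanged
  m2 <- cbind(A = exp(c(1, 2, 3)))
  expect_equal(normal_scores(as_cohort(m2, levels = 0)), z,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Pearson correlation of normal scores tracks raw-data Spearman", {
  net <- chain_net(c(0.5, 0.3))
  coh <- sample_cohort(net, 1000, levels = 5, seed = 1)
  z <- normal_scores(coh)
  expect_equal(
    cor(z)[upper.tri(diag(3))],
    cor(cohort_scores(coh), method = "spearman")[upper.tri(diag(3))],
    tolerance = 0.01
  )
})

test_that("the Gram-form CD lasso path agrees with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(42)
  X <- scale(matrix(rnorm(400 * 10), 400), scale = FALSE)
  y <- drop(X %*% c(1, -0.5, 0.3, rep(0, 7)) + rnorm(400))
  y <- y - mean(y)
  lam <- exp(seq(log(0.8), log(0.002), length.out = 40))
  b <- psychonectome:::cd_lasso_path(crossprod(X), drop(crossprod(X, y)),
                                     nrow(X), lam, rep(1, 10), 1e-10)
  g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(b - as.matrix(g$beta))), 1e-6)
  # penalty factors (glmnet normalizes them to sum to nvars)
  pf <- c(2, 1, 1, 0.5, 1, 1, 1, 3, 1, 1)
  b2 <- psychonectome:::cd_lasso_path(crossprod(X), drop(crossprod(X, y)),
                                      nrow(X), lam, pf / mean(pf), 1e-10)
  g2 <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                       intercept = FALSE, penalty.factor = pf,
                       thresh = 1e-14)
  expect_lt(max(abs(b2 - as.matrix(g2$beta))), 1e-6)
})

test_that("independent nodes yield an empty network", {
  net <- make_planted_network(nodes = c("A", "B"))
  z <- normal_scores(sample_cohort(net, 500, levels = 5, seed = 2))
  est <- estimate_network(z, seed = 1)
  expect_identical(network_density(est)$edges, 0L)
})

test_that("a planted 3-node chain is recovered with calibrated weights in most seeds", {
  net <- chain_net(c(0.3, 0.3))
  ok <- 0
  for (seed in 1:50) {
    coh <- sample_cohort(net, 2000, levels = 5, seed = seed)
    est <- estimate_network(normal_scores(coh), seed = seed)
    w <- est$weights
    hit <- abs(w["A", "B"] - 0.3) <= 0.07 &&
      abs(w["B", "C"] - 0.3) <= 0.07 &&
      abs(w["A", "C"]) < 1e-8
    if (hit) ok <- ok + 1
  }
  expect_gte(ok, 45)
})

test_that("with the penalty forced to zero, nodewise weights equal matrix-inversion partial correlations", {
  net <- make_planted_network(
    nodes = LETTERS[1:5],
    chains = list(list(nodes = LETTERS[1:5],
                       weights = c(0.3, 0.25, 0.2, 0.15))),
    negative_edges = list(list(from = "A", to = "D", weight = -0.2))
  )
  z <- normal_scores(sample_cohort(net, 5000, levels = 0, seed = 3))
  est0 <- estimate_network(z, lambda = 0)
  oracle <- unregularized_pcor(new_psy_corr(cor(z), "pearson"))
  expect_lt(max(abs(est0$weights - oracle$weights)), 0.01)
})

test_that("edge count is non-increasing in a global penalty multiplier", {
  net <- demo_scenario()$pre
  z <- normal_scores(sample_cohort(net, 300, levels = 5, seed = 4))
  lams <- c(0.005, 0.02, 0.05, 0.1, 0.2)
  counts <- vapply(lams, function(l) {
    network_density(estimate_network(z, lambda = l))$edges
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("estimates are symmetric, seed-deterministic, and AND is sparser than OR", {
  net <- demo_scenario()$pre
  z <- normal_scores(sample_cohort(net, 182, levels = 5, seed = 5))
  a <- estimate_network(z, seed = 9)
  b <- estimate_network(z, seed = 9)
  expect_identical(a$weights, b$weights)
  expect_identical(a$weights, t(a$weights))
  expect_true(all(abs(a$weights) < 1))
  or_net <- estimate_network(z, seed = 9, rule = "or")
  expect_gte(network_density(or_net)$edges, network_density(a)$edges)
})

test_that("estimator input validation catches the documented failure modes", {
  net <- chain_net(0.3)
  z <- normal_scores(sample_cohort(net, 25, levels = 5, seed = 6))
  expect_error(estimate_network(z, folds = 10), "3 \\* folds")
  z2 <- normal_scores(sample_cohort(net, 100, levels = 5, seed = 7))
  z2[1, 1] <- NA
  expect_error(estimate_network(z2), "missing")
})
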