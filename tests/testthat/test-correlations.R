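test_that("Spearman handles monotone pairs, hand-checkable ranks, and independence", {
  x <- c(-2, -1, 0, 1, 2)
  coh <- as_cohort(cbind(A = x, B = x^3), levels = 0)
  expect_equal(spearman_matrix(coh)$values["A", "B"], 1)

  # rank formula oracle: r = 1 - 6 sum(d^2) / (n (n^2 - 1)), no ties
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  d2 <- (rank(x) - rank(y))^2
  oracle <- 1 - 6 * sum(d2) / (5 * 24)
  coh2 <- as_cohort(cbind(A = x, B = y), levels = 5)
  expect_equal(unname(spearman_matrix(coh2)$values["A", "B"]), oracle)

  net <- make_planted_network(nodes = LETTERS[1:5])
  big <- sample_cohort(net, 5000, levels = 5, seed = 1)
  v <- spearman_matrix(big)$values
  expect_lt(max(abs(v[upper.tri(v)])), 0.05)
})

test_that("Spearman is invariant under strictly monotone per-column transforms", {
  net <- chain_net(c(0.4, 0.3))
  coh <- sample_cohort(net, 300, levels = 0, seed = 2)
  m <- cohort_scores(coh)
  m2 <- cbind(A = exp(m[, "A"]), B = m[, "B"]^3, C = qlogis(pnorm(m[, "C"])))
  expect_equal(
    spearman_matrix(as_cohort(m2, levels = 0))$values,
    spearman_matrix(coh)$values,
    tolerance = 1e-12
  )
})

test_that("constant columns are reported by name", {
  m <- cbind(A = c(1, 2, 3, 4), B = c(2, 2, 2, 2))
  expect_error(spearman_matrix(as_cohort(m, levels = 5)), "B")
})

test_that("polychoric recovers the latent correlation that Pearson-on-codes attenuates", {
  net <- chain_net(0.5)
  coh <- sample_cohort(net, 20000, levels = 5, seed = 3)
  rho <- polychoric_matrix(coh)$values["A", "B"]
  expect_equal(unname(rho), 0.5, tolerance = 0.03)
  expect_lt(cor(cohort_scores(coh))[1, 2], unname(rho))

  ind <- sample_cohort(make_planted_network(nodes = c("A", "B")),
                       10000, levels = 5, seed = 4)
  expect_equal(unname(polychoric_matrix(ind)$values["A", "B"]), 0,
               tolerance = 0.03)
})

test_that("the dichotomized case matches a brute-force tetrachoric grid search", {
  net <- chain_net(0.4)
  coh <- sample_cohort(net, 4000, levels = 2, seed = 5)
  est <- polychoric_matrix(coh)$values["A", "B"]
  # independent oracle: grid search over rho at step 1e-4 on the 2x2 table
  m <- cohort_scores(coh)
  tab <- table(m[, 1], m[, 2])
  a <- qnorm(mean(m[, 1] == 1))
  b <- qnorm(mean(m[, 2] == 1))
  # the likelihood is unimodal in rho; scan a bracket around the estimate
  grid <- seq(est - 0.2, est + 0.2, by = 1e-4)
  ll <- vapply(grid, function(r) {
    p11 <- mvtnorm::pmvnorm(upper = c(a, b),
                            corr = matrix(c(1, r, r, 1), 2))[1]
    p1 <- pnorm(a)
    p2 <- pnorm(b)
    # cells: (1,1), (1,2) = P(x1 <= a) - p11, (2,1) = P(x2 <= b) - p11, (2,2)
    p <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
    sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(pmax(p, 1e-12)))
  }, numeric(1))
  oracle <- grid[which.max(ll)]
  expect_equal(unname(est), oracle, tolerance = 1e-3)
})

test_that("polychoric rejects single-category margins", {
  m <- cbind(A = rep(2, 30), B = rep(1:5, 6))
  expect_error(polychoric_matrix(as_cohort(m, levels = 5)), "single observed")
})

test_that("standardized alpha follows its closed form and monotonicity", {
  eqmat <- function(k, r) {
    m <- matrix(r, k, k)
    diag(m) <- 1
    dimnames(m) <- list(paste0("i", 1:k), paste0("i", 1:k))
    m
  }
  expect_equal(cronbach_alpha(eqmat(2, 0.5)), 2 * 0.5 / 1.5)
  expect_equal(cronbach_alpha(eqmat(10, 0)), 0)
  # invert alpha = 0.87 at k = 20 and round-trip
  k <- 20
  alpha <- 0.87
  rbar <- alpha / (k - (k - 1) * alpha)
  expect_equal(cronbach_alpha(eqmat(k, rbar)), 0.87, tolerance = 1e-12)
  # monotone in rbar and in k (for rbar > 0)
  rs <- seq(0.1, 0.6, by = 0.1)
  a_r <- vapply(rs, function(r) cronbach_alpha(eqmat(5, r)), numeric(1))
  expect_true(all(diff(a_r) > 0))
  ks <- 2:8
  a_k <- vapply(ks, function(k) cronbach_alpha(eqmat(k, 0.3)), numeric(1))
  expect_true(all(diff(a_k) > 0))
  expect_error(cronbach_alpha(eqmat(4, -0.5)), "undefined")
})

test_that("the PSD repair clips negative eigenvalues, restores the unit diagonal, and is flagged", {
  m <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  dimnames(m) <- list(LETTERS[1:3], LETTERS[1:3])
  expect_lt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  rep <- psychonectome:::psd_repair(m)
  expect_true(rep$repaired)
  expect_gte(min(eigen(rep$values, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  expect_equal(unname(diag(rep$values)), rep(1, 3))
})

test_that("correlation matrices round-trip through CSV + sidecar", {
  net <- chain_net(c(0.4, 0.3))
  coh <- sample_cohort(net, 200, levels = 5, seed = 6)
  sp <- spearman_matrix(coh)
  path <- file.path(withr::local_tempdir(), "corr.csv")
  write_correlation(sp, path)
  back <- read_correlation(path)
  expect_equal(back$values, sp$values, tolerance = 1e-12)
  expect_identical(back$method, "spearman")
})
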