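test_that("independent nodes produce near-zero sample Spearman correlations", {
  net <- make_planted_network(nodes = LETTERS[1:6])
  coh <- sample_cohort(net, n = 5000, levels = 5, seed = 2)
  r <- spearman_matrix(coh)$values
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("a two-node continuous cohort reproduces its partial correlation as the Pearson r", {
  net <- chain_net(0.5)
  coh <- sample_cohort(net, n = 10000, levels = 0, seed = 3)
  r <- cor(cohort_scores(coh))[1, 2]
  expect_equal(r, 0.5, tolerance = 0.02)
})

test_that("5-level discretization attenuates Spearman as the Gaussian copula predicts", {
  net <- chain_net(0.5)
  coh <- sample_cohort(net, n = 10000, levels = 5, seed = 4)
  r_obs <- cor(cohort_scores(coh), method = "spearman")[1, 2]
  # Monte Carlo oracle: Spearman of the discretized latent bivariate normal
  oracle <- withr::with_seed(99, {
    z1 <- rnorm(1e6)
    z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(1e6)
    cuts <- qnorm(seq_len(4) / 5)
    cor(findInterval(z1, cuts), findInterval(z2, cuts), method = "spearman")
  })
  expect_equal(r_obs, oracle, tolerance = 0.04)
})

test_that("ordinal scores respect the Likert range and draws are seed-deterministic", {
  net <- demo_scenario()$pre
  a <- sample_cohort(net, n = 50, levels = 5, seed = 7)
  b <- sample_cohort(net, n = 50, levels = 5, seed = 7)
  expect_identical(cohort_scores(a), cohort_scores(b))
  v <- cohort_scores(a)
  expect_true(all(v == round(v) & v >= 1 & v <= 5))
  c2 <- sample_cohort(net, n = 50, levels = 5, seed = 8)
  expect_false(identical(cohort_scores(a), cohort_scores(c2)))
})

test_that("paired cohorts share subject-level dependence controlled by subject_rho", {
  net <- demo_scenario()$pre
  # rho = 0: occasions are independent
  pair0 <- make_pre_post(net, net, n = 5000, subject_rho = 0, seed = 5)
  z_pre <- attr(pair0$pre, "latent")
  z_post <- attr(pair0$post, "latent")
  cors0 <- vapply(seq_len(ncol(z_pre)),
                  function(j) cor(z_pre[, j], z_post[, j]), numeric(1))
  expect_lt(max(abs(cors0)), 0.05)
  # rho = 0.5 with identical networks: per-node latent correlation 0.5
  pair5 <- make_pre_post(net, net, n = 5000, subject_rho = 0.5, seed = 6)
  z_pre <- attr(pair5$pre, "latent")
  z_post <- attr(pair5$post, "latent")
  cors5 <- vapply(seq_len(ncol(z_pre)),
                  function(j) cor(z_pre[, j], z_post[, j]), numeric(1))
  expect_true(all(abs(cors5 - 0.5) < 0.03))
  expect_identical(pair5$pre$subject_id, pair5$post$subject_id)
  expect_error(make_pre_post(net, net, 100, subject_rho = 1), "\\[0, 1\\)")
})

test_that("each occasion keeps its own marginal structure under pairing", {
  sc <- demo_scenario()
  pair <- make_pre_post(sc$pre, sc$post, n = 4000, subject_rho = 0.5,
                        levels = 0, seed = 9)
  for (occ in c("pre", "post")) {
    emp <- cor(attr(pair[[occ]], "latent"))
    expect_lt(max(abs(emp - implied_correlation(sc[[occ]]))), 2 * 3 / sqrt(4000))
  }
})

test_that("MCAR masking hits the requested rate, is value-independent, and validates inputs", {
  net <- make_planted_network(nodes = LETTERS[1:25])
  coh <- sample_cohort(net, n = 1000, levels = 5, seed = 10)
  expect_identical(
    sum(is.na(cohort_scores(apply_mcar(coh, 0, seed = 1)))), 0L
  )
  masked <- apply_mcar(coh, 0.108, seed = 11)
  expect_lt(abs(mean(is.na(cohort_scores(masked))) - 0.108), 0.006)
  expect_error(apply_mcar(coh, 0.6), "\\[0, 0.5\\]")

  # value-independence: masked vs unmasked means agree at alpha = .01
  small <- sample_cohort(net, n = 400, levels = 5, seed = 12)
  n_flagged <- 0
  for (seed in 1:30) {
    m <- apply_mcar(small, 0.108, seed = seed)
    v <- cohort_scores(small)
    na <- is.na(cohort_scores(m))
    p <- stats::t.test(v[na], v[!na])$p.value
    if (p < 0.01) n_flagged <- n_flagged + 1
  }
  expect_lte(n_flagged, 2)
})

test_that("cohorts round-trip through CSV + JSON sidecar", {
  net <- chain_net(c(0.3, 0.2))
  coh <- apply_mcar(sample_cohort(net, 40, levels = 5, seed = 3), 0.1, seed = 4)
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort(coh, path, extra = list(seed = 3))
  back <- read_cohort(path)
  expect_identical(cohort_scores(back), cohort_scores(coh))
  expect_identical(cohort_occasion(back), cohort_occasion(coh))
  expect_identical(cohort_levels(back), cohort_levels(coh))
})
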