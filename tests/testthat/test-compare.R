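make_cohort_pair <- function(pre_mat, post_mat, levels = 0) {
  list(
    pre = as_cohort(pre_mat, occasion = "pre", levels = levels),
    post = as_cohort(post_mat, occasion = "post", levels = levels)
  )
}

test_that("paired t matches the hand-computed example and flags degenerate differences", {
  pre <- cbind(A = c(1, 2, 3, 4), B = c(2, 2, 2, 2))
  post <- cbind(A = c(2, 2, 4, 4), B = c(2, 2, 2, 2)) # diffs A: 1,0,1,0
  cp <- make_cohort_pair(pre, post, levels = 5)
  res <- paired_t(cp$pre, cp$post)
  a <- res[res$node == "A", ]
  expect_equal(a$t, 0.5 / (sd(c(1, 0, 1, 0)) / 2), tolerance = 1e-12)
  expect_equal(a$t, 1.732, tolerance = 1e-3)
  expect_identical(a$df, 3)
  b <- res[res$node == "B", ]
  expect_true(is.na(b$t))
  expect_identical(b$flag, "zero-variance differences")
})

test_that("paired t is antisymmetric and agrees with stats::t.test", {
  net <- chain_net(c(0.3, 0.3))
  pair <- make_pre_post(net, net, 60, subject_rho = 0.4, seed = 1)
  fwd <- paired_t(pair$pre, pair$post)
  rev <- paired_t(pair$post, pair$pre)
  expect_equal(fwd$t, -rev$t, tolerance = 1e-12)
  # cross-check one node against the reference implementation
  d_pre <- cohort_scores(pair$pre)[, "A"]
  d_post <- cohort_scores(pair$post)[, "A"]
  ref <- stats::t.test(d_post, d_pre, paired = TRUE)
  expect_equal(fwd$t[fwd$node == "A"], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(fwd$p[fwd$node == "A"], ref$p.value, tolerance = 1e-10)
})

test_that("subjects are matched by id, not position", {
  pre <- tibble::tibble(subject_id = c("s1", "s2", "s3"), A = c(1, 2, 3))
  post <- tibble::tibble(subject_id = c("s3", "s1", "s2"), A = c(4, 2, 3))
  res <- paired_t(as_cohort(pre, "pre", 5), as_cohort(post, "post", 5))
  # matched diffs: s1 2-1=1, s2 3-2=1, s3 4-3=1 -> zero variance, flagged
  expect_true(is.na(res$t))
  expect_equal(res$post_mean - res$pre_mean, 1)
})

test_that("centrality deltas are exact and top movers are ranked by absolute change", {
  net_a <- random_network(8, density = 0.4, seed = 2)
  tab_a <- centrality_table(net_a)
  ch0 <- centrality_change(tab_a, tab_a)
  expect_true(all(ch0$deltas$strength == 0))
  # give one node three strong new edges
  w <- net_a$weights
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.5
  w[1, 4] <- w[4, 1] <- 0.5
  tab_b <- centrality_table(new_psy_network(w))
  ch <- centrality_change(tab_a, tab_b)
  top_strength <- ch$top_movers[ch$top_movers$index == "strength", ]
  expect_identical(top_strength$node[1], net_a$nodes[1])
  # all-positive layers: delta(EI) == delta(strength)
  pos_a <- random_network(6, density = 0.5, seed = 3, signed = FALSE)
  pos_b <- random_network(6, density = 0.5, seed = 4, signed = FALSE)
  chp <- centrality_change(centrality_table(pos_a), centrality_table(pos_b))
  expect_equal(chp$deltas$expected_influence, chp$deltas$strength,
               tolerance = 1e-12)
})

test_that("layer correlation is 1 on identical layers and flags zero-variance vectors", {
  net <- random_network(10, density = 0.4, seed = 5)
  res <- layer_correlation(net, net)
  expect_equal(res$correlation[res$quantity == "edge_weights"], 1,
               tolerance = 1e-12)
  empty <- new_psy_network(matrix(0, 10, 10,
                                  dimnames = dimnames(net$weights)))
  res2 <- layer_correlation(net, empty)
  expect_true(is.na(res2$correlation[res2$quantity == "edge_weights"]))
  expect_identical(res2$flag[res2$quantity == "edge_weights"],
                   "zero-variance vector")
})

test_that("independent random layers decorrelate while a true reorganization stays below self-similarity", {
  cors <- vapply(1:25, function(seed) {
    a <- random_network(25, density = 0.3, seed = seed)
    b <- random_network(25, density = 0.3, seed = seed + 1000)
    layer_correlation(a, b)$correlation[1]
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.15)

  # estimated chains-pre vs blocks-post: cross-layer edge correlation low
  sc <- demo_scenario()
  pair <- make_pre_post(sc$pre, sc$post, 400, subject_rho = 0.5, seed = 6)
  net_pre <- estimate_network(pair$pre, seed = 7)
  net_post <- estimate_network(pair$post, seed = 7)
  cross <- layer_correlation(net_pre, net_post)$correlation[1]
  expect_lt(cross, 0.5)
  # within-layer self-correlation against an independent draw of pre
  pair2 <- make_pre_post(sc$pre, sc$post, 400, subject_rho = 0.5, seed = 8)
  net_pre2 <- estimate_network(pair2$pre, seed = 7)
  self <- layer_correlation(net_pre, net_pre2)$correlation[1]
  expect_gt(self, cross)
})

test_that("the bundled report joins tests, deltas, correlations and partition agreement", {
  sc <- demo_scenario()
  pair <- make_pre_post(sc$pre, sc$post, 150, subject_rho = 0.5, seed = 9)
  net_pre <- estimate_network(pair$pre, seed = 10)
  net_post <- estimate_network(pair$post, seed = 10)
  p_pre <- spinglass(net_pre, seed = 11, restarts = 3)
  p_post <- spinglass(net_post, seed = 11, restarts = 3)
  rep <- compare_pre_post(pair$pre, pair$post, net_pre, net_post,
                          p_pre, p_post)
  expect_identical(nrow(rep$tests), 25L)
  expect_true(all(rep$tests$df == 149))
  expect_identical(nrow(rep$deltas), 25L)
  expect_true(all(c("ari", "nmi") %in% names(rep$partition_agreement)))
})
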