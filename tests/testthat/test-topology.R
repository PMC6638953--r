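mini_net <- function() {
  w <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  w["A", "B"] <- w["B", "A"] <- 0.3
  w["A", "C"] <- w["C", "A"] <- -0.2
  new_psy_network(w)
}

test_that("expected influence sums signed weights; strength sums absolute weights", {
  net <- mini_net()
  expect_equal(unname(expected_influence(net)["A"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(node_strength(net)["A"]), 0.5, tolerance = 1e-12)
  iso <- new_psy_network(matrix(0, 2, 2))
  expect_identical(unname(expected_influence(iso)), c(0, 0))
  expect_identical(unname(node_strength(iso)), c(0, 0))
})

test_that("EI equals strength exactly on all-positive networks, and strength >= |EI| always", {
  for (seed in 1:10) {
    pos <- random_network(7, density = 0.5, seed = seed, signed = FALSE)
    expect_identical(expected_influence(pos), node_strength(pos))
    sgn <- random_network(7, density = 0.5, seed = seed + 100)
    expect_true(all(node_strength(sgn) - abs(expected_influence(sgn)) >= -1e-12))
  }
})

test_that("degree and hubs: star center dominates; empty network has no hubs", {
  w <- matrix(0, 6, 6)
  w[1, 2:6] <- w[2:6, 1] <- 0.3
  star <- new_psy_network(w)
  expect_identical(unname(node_degree(star)), c(5L, rep(1L, 5)))
  expect_identical(hub_nodes(star), star$nodes[1])
  expect_identical(hub_nodes(new_psy_network(matrix(0, 4, 4))), character(0))
  # random graph degrees match the adjacency count oracle
  net <- random_network(10, density = 0.3, seed = 5)
  expect_identical(unname(node_degree(net)),
                   unname(as.integer(rowSums(abs(net$weights) >= 1e-8))))
})

test_that("Onnela clustering: equal-weight triangle is 1, star center 0, random graphs match the triple-enumeration oracle", {
  tri <- new_psy_network(matrix(0.2, 3, 3) - diag(0.2, 3))
  expect_equal(unname(weighted_clustering(tri)), rep(1, 3), tolerance = 1e-12)
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- w[2:5, 1] <- 0.4
  expect_equal(unname(weighted_clustering(new_psy_network(w))[1]), 0)
  for (seed in 1:20) {
    net <- random_network(7, density = 0.5, seed = seed)
    expect_equal(unname(weighted_clustering(net)),
                 brute_clustering(net$weights), tolerance = 1e-12)
  }
})

test_that("efficiency: dyad closed form, disconnected zero, random graphs match all-pairs shortest-path oracle", {
  w <- matrix(c(0, 0.4, 0.4, 0), 2)
  expect_equal(network_efficiency(new_psy_network(w))$global, 0.4,
               tolerance = 1e-12)
  expect_identical(network_efficiency(new_psy_network(matrix(0, 5, 5)))$global, 0)
  for (seed in 1:20) {
    net <- random_network(6, density = 0.4, seed = seed + 40)
    eff <- network_efficiency(net)
    oracle <- brute_efficiency(net$weights)
    expect_equal(eff$global, oracle$global, tolerance = 1e-12)
    expect_equal(unname(eff$nodal), oracle$nodal, tolerance = 1e-12)
  }
})

test_that("removing an edge never increases degree, strength, or global efficiency", {
  for (seed in 1:10) {
    net <- random_network(8, density = 0.5, seed = seed + 7)
    ed <- tidy(net)
    if (!nrow(ed)) next
    pick <- withr::with_seed(seed, sample(nrow(ed), 1))
    w2 <- net$weights
    w2[ed$from[pick], ed$to[pick]] <- 0
    w2[ed$to[pick], ed$from[pick]] <- 0
    net2 <- new_psy_network(w2)
    expect_true(all(node_degree(net2) <= node_degree(net)))
    expect_true(all(node_strength(net2) <= node_strength(net) + 1e-12))
    expect_lte(network_efficiency(net2)$global,
               network_efficiency(net)$global + 1e-12)
  }
})

test_that("the centrality table satisfies its range invariants", {
  net <- random_network(12, density = 0.4, seed = 11)
  tab <- centrality_table(net)
  expect_true(all(tab$strength >= abs(tab$expected_influence) - 1e-12))
  expect_true(all(tab$degree >= 0 & tab$degree <= 11))
  expect_true(all(tab$clustering >= 0 & tab$clustering <= 1))
  expect_true(all(tab$efficiency >= 0))
  expect_gte(attr(tab, "global_efficiency"), 0)
})

test_that("find_paths returns a pure chain whole and nothing below threshold", {
  w <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  for (i in 1:3) w[i, i + 1] <- w[i + 1, i] <- 0.3
  net <- new_psy_network(w)
  res <- find_paths(net)
  expect_identical(nrow(res), 1L)
  expect_identical(res$path[[1]], LETTERS[1:4])
  expect_equal(res$total_weight, 0.9, tolerance = 1e-12)
  expect_identical(nrow(find_paths(net, threshold = 0.5)), 0L)
})

test_that("find_paths recovers the two planted chains of the demo truth as the top disjoint paths", {
  truth <- demo_scenario()$pre
  net <- new_psy_network(truth$pcor, layer = "truth")
  res <- find_paths(net)
  expect_gte(nrow(res), 2)
  expect_identical(res$path[[1]],
                   c("FFMQ-O", "MAIA", "EQ", "NAS", "SCS-M", "SCS-K", "SCS-H"))
  expect_identical(res$path[[2]],
                   c("DASS-A", "DASS-S", "DASS-D", "RRS-B", "RRS-R"))
  # selected paths are mutually node-disjoint and above threshold
  expect_length(intersect(res$path[[1]], res$path[[2]]), 0)
  expect_true(all(abs(unlist(res$step_weights)) >= 0.15))
})

test_that("find_paths is invariant to node relabeling up to the permutation", {
  net <- random_network(8, density = 0.35, seed = 21)
  res <- find_paths(net, threshold = 0.2)
  perm <- withr::with_seed(3, sample(8))
  w2 <- net$weights[perm, perm]
  map <- setNames(colnames(net$weights)[perm], colnames(net$weights)[perm])
  res2 <- find_paths(new_psy_network(w2), threshold = 0.2)
  norm_paths <- function(r) {
    sort(vapply(r$path, function(p) paste(sort(p), collapse = "|"), character(1)))
  }
  expect_identical(norm_paths(res), norm_paths(res2))
  expect_equal(sort(res$total_weight), sort(res2$total_weight),
               tolerance = 1e-12)
})

test_that("FR layouts are deterministic, unit-square scaled, and geometry reflects cohesion", {
  net <- random_network(9, density = 0.4, seed = 12)
  a <- fr_layout(net, seed = 5)
  b <- fr_layout(net, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$x >= 0 & a$x <= 1 & a$y >= 0 & a$y <= 1))
  expect_identical(fr_layout(new_psy_network(matrix(0, 1, 1),
                                             layer = "x"), seed = 1)$x, 0)
  # two cliques bridged weakly: within-clique distances < between
  w <- matrix(0, 10, 10)
  w[1:5, 1:5] <- 0.4
  w[6:10, 6:10] <- 0.4
  diag(w) <- 0
  w[5, 6] <- w[6, 5] <- 0.05
  xy <- fr_layout(new_psy_network(w), seed = 2)
  dmat <- as.matrix(dist(cbind(xy$x, xy$y)))
  within <- c(dmat[1:5, 1:5][upper.tri(diag(5))],
              dmat[6:10, 6:10][upper.tri(diag(5))])
  between <- dmat[1:5, 6:10]
  expect_lt(mean(within), mean(between))
})
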