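#' Node centrality indices of a signed weighted network
#'
#' `expected_influence()` is the signed one-step sum of a node's edge
#' weights; `node_strength()` the sum of absolute weights;
#' `node_degree()` the count of edges with `|w| >= 1e-8`; `hub_nodes()`
#' the nodes whose degree reaches the chosen percentile of the degree
#' distribution (ties included); `weighted_clustering()` the Onnela
#' weighted clustering coefficient on max-normalized absolute weights (the
#' Barrat variant is available); `network_efficiency()` the global and
#' nodal efficiencies with edge lengths `1 / |w|`.
#'
#' @param net a `psy_network`.
#' @return Named numeric (or integer) vector over nodes;
#'   `network_efficiency()` returns `list(global = , nodal = )`;
#'   `hub_nodes()` a character vector.
#' @name centrality
NULL

#' @rdname centrality
#' @export
expected_influence <- function(net) {
  w <- net$weights
  w[abs(w) < EDGE_EPS] <- 0
  rowSums(w)
}

#' @rdname centrality
#' @export
node_strength <- function(net) {
  w <- abs(net$weights)
  w[w < EDGE_EPS] <- 0
  rowSums(w)
}

#' @rdname centrality
#' @export
node_degree <- function(net) {
  a <- abs(net$weights) >= EDGE_EPS
  setNames(as.integer(rowSums(a)), net$nodes)
}

#' @rdname centrality
#' @param percentile hub cutoff on the degree distribution (default 0.9).
#' @export
hub_nodes <- function(net, percentile = 0.9) {
  d <- node_degree(net)
  if (all(d == 0)) return(character(0))
  names(d)[d >= quantile(d, percentile)]
}

#' @rdname centrality
#' @param variant `"onnela"` (default) or `"barrat"`.
#' @export
weighted_clustering <- function(net, variant = c("onnela", "barrat")) {
  variant <- match.arg(variant)
  w <- abs(net$weights)
  w[w < EDGE_EPS] <- 0
  d <- rowSums(w > 0)
  k <- ncol(w)
  out <- setNames(numeric(k), net$nodes)
  if (max(w) == 0) return(out)
  if (variant == "onnela") {
    wh <- (w / max(w))^(1 / 3)
    num <- diag(wh %*% wh %*% wh)
    denom <- d * (d - 1)
    out[denom > 0] <- num[denom > 0] / denom[denom > 0]
  } else {
    a <- (w > 0) + 0
    s <- rowSums(w)
    num <- diag((w %*% a + a %*% w) %*% a) / 2
    denom <- s * (d - 1)
    out[denom > 0] <- num[denom > 0] / denom[denom > 0]
  }
  pmin(pmax(out, 0), 1)
}

#' @rdname centrality
#' @export
network_efficiency <- function(net) {
  k <- length(net$nodes)
  if (k < 2) return(list(global = 0, nodal = setNames(numeric(k), net$nodes)))
  g <- as_igraph(net, absolute = TRUE)
  if (igraph::ecount(g) == 0) {
    return(list(global = 0, nodal = setNames(numeric(k), net$nodes)))
  }
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  d <- d[net$nodes, net$nodes]
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  list(
    global = sum(inv) / (k * (k - 1)),
    nodal = setNames(rowSums(inv) / (k - 1), net$nodes)
  )
}

#' Centrality table of a network layer
#'
#' One row per node with expected influence, strength, degree, Onnela
#' clustering and nodal efficiency, plus the network's global efficiency
#' and layer tag as attributes and repeated columns for convenience.
#'
#' @param net a `psy_network`.
#' @param clustering_variant passed to [weighted_clustering()].
#' @return A tibble of class `psy_centrality`.
#' @export
centrality_table <- function(net, clustering_variant = "onnela") {
  eff <- network_efficiency(net)
  out <- tibble(
    node = net$nodes,
    expected_influence = unname(expected_influence(net)),
    strength = unname(node_strength(net)),
    degree = unname(node_degree(net)),
    clustering = unname(weighted_clustering(net, clustering_variant)),
    efficiency = unname(eff$nodal)
  )
  structure(
    out,
    layer = net$layer, global_efficiency = eff$global,
    clustering_variant = clustering_variant,
    class = c("psy_centrality", class(out))
  )
}

#' @rdname tidy-psychonectome
#' @export
glance.psy_centrality <- function(x, ...) {
  tibble(
    layer = attr(x, "layer"),
    global_efficiency = attr(x, "global_efficiency"),
    mean_expected_influence = mean(x$expected_influence),
    mean_strength = mean(x$strength),
    hubs = paste(x$node[x$degree >= quantile(x$degree, 0.9)], collapse = ",")
  )
}

#' Fruchterman-Reingold layout of a network
#'
#' Force-directed layout in which attraction grows with `|w|`, so strongly
#' or densely connected nodes are drawn close together. Coordinates are
#' rescaled to the unit square; a single node sits at the origin.
#'
#' @param net a `psy_network`.
#' @param iterations number of FR iterations.
#' @param seed integer seed (layouts are deterministic given the seed).
#' @return A tibble with columns `node`, `x`, `y`.
#' @export
fr_layout <- function(net, iterations = 500, seed = 1) {
  k <- length(net$nodes)
  if (k == 1) return(tibble(node = net$nodes, x = 0, y = 0))
  g <- as_igraph(net, absolute = TRUE)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(
    g, niter = iterations,
    weights = if (igraph::ecount(g)) igraph::E(g)$weight else NULL
  ))
  rng <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0.5, length(v)) else (v - min(v)) / r
  }
  tibble(node = igraph::V(g)$name, x = rng(xy[, 1]), y = rng(xy[, 2])) |>
    dplyr::slice(match(net$nodes, igraph::V(g)$name))
}
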