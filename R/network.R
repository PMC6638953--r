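# Absent-edge threshold: LASSO produces exact zeros, the epsilon only
# guards floating-point noise.
EDGE_EPS <- 1e-8

#' Weighted signed network objects
#'
#' A `psy_network` wraps a symmetric signed weight matrix (zero diagonal,
#' entries in (-1, 1), partial-correlation scale) over labeled nodes, plus a
#' layer tag (`"pre"`, `"post"`, ...) and estimator metadata. Entries with
#' `|w| < 1e-8` count as absent edges everywhere.
#'
#' @param weights symmetric numeric matrix with dimnames.
#' @param layer layer tag.
#' @param meta named list of estimator metadata.
#' @return A `psy_network`.
#' @export
new_psy_network <- function(weights, layer = "other", meta = list()) {
  check_square_symmetric(weights, "weights", tol = 1e-8)
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(abs(weights) >= 1)) abort("Edge weights must lie in (-1, 1).")
  if (is.null(colnames(weights))) {
    colnames(weights) <- rownames(weights) <- sprintf("V%02d", seq_len(ncol(weights)))
  }
  structure(
    list(weights = weights, nodes = colnames(weights), layer = layer,
         meta = meta),
    class = "psy_network"
  )
}

#' @export
print.psy_network <- function(x, ...) {
  d <- network_density(x)
  cat(sprintf(
    "<psy_network> layer=%s, %d nodes, %d/%d edges (%.2f%%)\n",
    x$layer, length(x$nodes), d$edges, d$potential, d$percent
  ))
  invisible(x)
}

#' Tidiers for psychonectome objects
#'
#' [generics::tidy()] returns the object's long-form tibble (edges for
#' networks and planted networks, node pairs for correlation matrices,
#' node/community rows for partitions); [generics::glance()] returns a
#' one-row summary.
#'
#' @param x a psychonectome object.
#' @param ... unused.
#' @name tidy-psychonectome
NULL

#' @rdname tidy-psychonectome
#' @export
tidy.psy_network <- function(x, ...) {
  up <- upper_pairs(x$nodes)
  w <- x$weights[cbind(up$i, up$j)]
  up |>
    mutate(weight = w) |>
    filter(abs(.data$weight) >= EDGE_EPS) |>
    select("from", "to", "weight")
}

#' @rdname tidy-psychonectome
#' @export
glance.psy_network <- function(x, ...) {
  d <- network_density(x)
  tibble(
    layer = x$layer, nodes = length(x$nodes), edges = d$edges,
    potential = d$potential, percent = d$percent,
    positive = sum(tidy.psy_network(x)$weight > 0),
    negative = sum(tidy.psy_network(x)$weight < 0)
  )
}

#' Edge density of a network
#'
#' @param net a `psy_network`.
#' @return A list with `edges` (entries with `|w| >= 1e-8` above the
#'   diagonal), `potential` (`k(k-1)/2`), and `percent` (rounded to 2
#'   decimals).
#' @export
#' @examples
#' # 25 nodes leave 300 potential edges
#' network_density(new_psy_network(matrix(0, 25, 25)))$potential
network_density <- function(net) {
  k <- length(net$nodes)
  w <- net$weights[upper.tri(net$weights)]
  edges <- sum(abs(w) >= EDGE_EPS)
  potential <- k * (k - 1) / 2
  list(edges = edges, potential = potential,
       percent = round(100 * edges / potential, 2))
}

#' Exact partial correlations from a correlation matrix
#'
#' Inverts the correlation matrix and standardizes the negated inverse:
#' `w[i, j] = -K[i, j] / sqrt(K[i, i] * K[j, j])` with `K = R^-1`. This is
#' the unregularized Gaussian-graphical-model solution and the oracle
#' against which the nodewise LASSO estimator is checked.
#'
#' @param corr a `psy_corr` or a positive-definite correlation matrix.
#' @param layer layer tag for the result.
#' @return A `psy_network`.
#' @export
unregularized_pcor <- function(corr, layer = "other") {
  R <- if (inherits(corr, "psy_corr")) corr$values else corr
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-12) {
    abort("Correlation matrix is singular; use the regularized estimator.")
  }
  K <- solve(R)
  w <- -K / sqrt(tcrossprod(diag(K)))
  diag(w) <- 0
  new_psy_network((w + t(w)) / 2, layer = layer,
                  meta = list(estimator = "unregularized"))
}

#' Convert a network to an igraph graph
#'
#' Edges are the entries with `|w| >= 1e-8`; the signed weight is stored in
#' the `weight` edge attribute.
#'
#' @param net a `psy_network`.
#' @param absolute use `|w|` as the weight attribute.
#' @return An `igraph` object.
#' @export
as_igraph <- function(net, absolute = FALSE) {
  edges <- tidy.psy_network(net)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  if (absolute) igraph::E(g)$weight <- abs(igraph::E(g)$weight)
  g
}

#' Write / read a network
#'
#' `format = "tsv"` writes a weighted edge list (`node_i`, `node_j`,
#' `weight`), `"csv"` the full weight matrix with node labels, and
#' `"graphml"` a GraphML file with a signed `weight` edge attribute. All
#' three round-trip losslessly to 1e-12.
#'
#' @param net a `psy_network`.
#' @param path output file.
#' @param format one of `"tsv"`, `"csv"`, `"graphml"`.
#' @export
write_network <- function(net, path, format = c("tsv", "csv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- tidy.psy_network(net)
    readr::write_tsv(setNames(edges, c("node_i", "node_j", "weight")), path)
    jsonlite::write_json(
      list(nodes = net$nodes, layer = net$layer, meta = net$meta),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  } else if (format == "csv") {
    df <- as.data.frame(net$weights)
    readr::write_csv(tibble(node = net$nodes, !!!df), path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @param layer layer tag for the network read back (ignored for `"tsv"`,
#'   whose sidecar stores it).
#' @export
read_network <- function(path, format = c("tsv", "csv", "graphml"),
                         layer = "other") {
  format <- match.arg(format)
  if (format == "tsv") {
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    edges <- readr::read_tsv(path, show_col_types = FALSE)
    k <- length(side$nodes)
    w <- matrix(0, k, k, dimnames = list(side$nodes, side$nodes))
    if (nrow(edges)) {
      w[cbind(edges$node_i, edges$node_j)] <- edges$weight
      w[cbind(edges$node_j, edges$node_i)] <- edges$weight
    }
    new_psy_network(w, layer = side$layer,
                    meta = as.list(side$meta))
  } else if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    w <- as.matrix(df[, -1])
    rownames(w) <- df$node
    new_psy_network(w, layer = layer)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    labs <- igraph::V(g)$name
    w <- matrix(0, length(labs), length(labs),
                dimnames = list(labs, labs))
    el <- igraph::as_data_frame(g, what = "edges")
    if (nrow(el)) {
      w[cbind(el$from, el$to)] <- el$weight
      w[cbind(el$to, el$from)] <- el$weight
    }
    new_psy_network(w, layer = layer)
  }
}
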