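#' Build a planted partial-correlation network
#'
#' Assembles a ground-truth sparse signed Gaussian graphical model from
#' chain, block and single-edge specifications. The target partial
#' correlations are written into a precision matrix `K` with unit diagonal
#' and `K[i, j] = -pcor[i, j]`. If the assembled `K` is not positive
#' definite it is repaired by the smallest ridge inflation `K + d*I` that
#' lifts the minimum eigenvalue to `1e-6`, then rescaled back to unit
#' diagonal; the *realized* partial correlations (which may be slightly
#' smaller in magnitude than requested) are the declared truth used by all
#' downstream recovery checks.
#'
#' Explicit edges (chains and `negative_edges`) take precedence over block
#' fill-in, so a chain may run inside a community block; two explicit
#' specifications of the same pair with different weights are an error.
#'
#' @param nodes node labels (character) or a node count `k` (labels become
#'   `"V01"...`); defaults to the 25 subscale acronyms of
#'   [psychonectome_nodes()].
#' @param chains list of chains, each `list(nodes = c(...), weights = c(...))`
#'   with one weight per consecutive pair.
#' @param blocks list of community blocks, each `list(nodes = c(...),
#'   weight = w)`; every within-block pair not already set gets `w`, and the
#'   block defines one planted community (remaining nodes become singleton
#'   communities).
#' @param negative_edges list of single edges, each `list(from =, to =,
#'   weight =)`; despite the name any sign in (-1, 1) is accepted.
#' @param description free-text tag stored on the object.
#' @return A `planted_network`: list with `nodes`, `pcor` (realized partial
#'   correlations), `communities` (named integer vector, ids from 0),
#'   `requested` (pre-repair pcor), `ridge` (the delta used, 0 if none) and
#'   `description`.
#' @export
#' @examples
#' net <- make_planted_network(
#'   nodes = c("A", "B", "C"),
#'   chains = list(list(nodes = c("A", "B", "C"), weights = c(0.3, 0.3)))
#' )
#' net$pcor
make_planted_network <- function(nodes = psychonectome_nodes(),
                                 chains = list(),
                                 blocks = list(),
                                 negative_edges = list(),
                                 description = "") {
  if (is.numeric(nodes) && length(nodes) == 1) {
    nodes <- sprintf("V%02d", seq_len(nodes))
  }
  nodes <- as.character(nodes)
  k <- length(nodes)
  if (anyDuplicated(nodes)) abort("Node labels must be unique.")

  pcor <- matrix(0, k, k, dimnames = list(nodes, nodes))
  explicit <- matrix(FALSE, k, k)

  idx_of <- function(lab) {
    i <- match(lab, nodes)
    if (anyNA(i)) abort(sprintf("Unknown node label(s): %s",
                                paste(lab[is.na(i)], collapse = ", ")))
    i
  }
  check_w <- function(w) {
    if (any(!is.finite(w)) || any(abs(w) >= 1)) {
      abort("Edge weights must lie strictly inside (-1, 1).")
    }
  }
  set_edge <- function(i, j, w, explicit_edge) {
    if (i == j) abort("Self-edges are not allowed.")
    if (explicit_edge) {
      if (explicit[i, j] && pcor[i, j] != w) {
        abort(sprintf("Conflicting weights for edge %s--%s (%.3f vs %.3f).",
                      nodes[i], nodes[j], pcor[i, j], w))
      }
      pcor[i, j] <<- w
      pcor[j, i] <<- w
      explicit[i, j] <<- TRUE
      explicit[j, i] <<- TRUE
    } else if (!explicit[i, j]) {
      if (pcor[i, j] != 0 && pcor[i, j] != w) {
        abort(sprintf("Conflicting block weights for edge %s--%s (%.3f vs %.3f).",
                      nodes[i], nodes[j], pcor[i, j], w))
      }
      pcor[i, j] <<- w
      pcor[j, i] <<- w
    }
  }

  for (ch in chains) {
    v <- idx_of(ch$nodes)
    w <- ch$weights
    if (length(w) != length(v) - 1) {
      abort("A chain needs one weight per consecutive node pair.")
    }
    check_w(w)
    for (s in seq_along(w)) set_edge(v[s], v[s + 1], w[s], TRUE)
  }
  for (e in negative_edges) {
    check_w(e$weight)
    set_edge(idx_of(e$from), idx_of(e$to), e$weight, TRUE)
  }
  for (b in blocks) {
    v <- idx_of(b$nodes)
    check_w(b$weight)
    if (length(v) >= 2) {
      for (p in seq_len(length(v) - 1)) {
        for (q in seq(p + 1, length(v))) set_edge(v[p], v[q], b$weight, FALSE)
      }
    }
  }

  requested <- pcor
  K <- diag(k) - pcor
  dimnames(K) <- dimnames(pcor)
  delta <- ridge_to_pd(K, floor = 1e-6)
  if (delta > 0) {
    K <- K + delta * diag(k)
    d <- sqrt(diag(K))
    K <- K / tcrossprod(d) # rescale to unit diagonal
  }
  realized <- -K
  diag(realized) <- 0

  communities <- rep(NA_integer_, k)
  names(communities) <- nodes
  cid <- 0L
  for (b in blocks) {
    v <- idx_of(b$nodes)
    free <- v[is.na(communities[v])]
    if (length(free)) {
      communities[free] <- cid
      cid <- cid + 1L
    }
  }
  for (i in which(is.na(communities))) {
    communities[i] <- cid
    cid <- cid + 1L
  }

  structure(
    list(
      nodes = nodes, pcor = realized, communities = communities,
      requested = requested, ridge = delta, description = description
    ),
    class = "planted_network"
  )
}

#' Correlation matrix implied by a planted network
#'
#' Inverts the unit-diagonal precision matrix encoded by the planted partial
#' correlations and standardizes the result; this is the latent Gaussian
#' correlation used by [sample_cohort()].
#'
#' @param net a `planted_network`.
#' @return A symmetric positive-definite correlation matrix.
#' @export
implied_correlation <- function(net) {
  stopifnot(inherits(net, "planted_network"))
  K <- diag(length(net$nodes)) - net$pcor
  R <- stats::cov2cor(solve(K))
  dimnames(R) <- list(net$nodes, net$nodes)
  (R + t(R)) / 2
}

#' @export
print.planted_network <- function(x, ...) {
  k <- length(x$nodes)
  ne <- sum(abs(x$pcor[upper.tri(x$pcor)]) > 0)
  cat(sprintf(
    "<planted_network> %d nodes, %d edges, %d communities%s\n",
    k, ne, length(unique(x$communities)),
    if (x$ridge > 0) sprintf(" (PD ridge %.2e)", x$ridge) else ""
  ))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

#' @rdname tidy-psychonectome
#' @export
tidy.planted_network <- function(x, ...) {
  up <- upper_pairs(x$nodes)
  w <- x$pcor[cbind(up$i, up$j)]
  up |>
    mutate(weight = w) |>
    filter(.data$weight != 0) |>
    select("from", "to", "weight")
}

#' Write / read a planted network
#'
#' `write_planted_network()` writes a tab-separated weighted edge list
#' (`node_i`, `node_j`, `weight`) plus a JSON sidecar (`<path>.json`) holding
#' the full realized matrix, the community labels and the description;
#' `read_planted_network()` reads the pair back.
#'
#' @param net a `planted_network`.
#' @param path file path of the edge list (`.tsv`).
#' @return `write_planted_network()` returns `path` invisibly;
#'   `read_planted_network()` returns a `planted_network`.
#' @export
write_planted_network <- function(net, path) {
  stopifnot(inherits(net, "planted_network"))
  edges <- tidy.planted_network(net)
  readr::write_tsv(
    setNames(edges, c("node_i", "node_j", "weight")), path
  )
  jsonlite::write_json(
    list(
      nodes = net$nodes,
      pcor = net$pcor,
      communities = as.list(net$communities),
      ridge = net$ridge,
      description = net$description
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_planted_network
#' @export
read_planted_network <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pcor <- as.matrix(meta$pcor)
  dimnames(pcor) <- list(meta$nodes, meta$nodes)
  structure(
    list(
      nodes = meta$nodes, pcor = pcor,
      communities = setNames(as.integer(unlist(meta$communities)),
                             names(meta$communities)),
      requested = pcor, ridge = meta$ridge, description = meta$description
    ),
    class = "planted_network"
  )
}

#' Random planted network with degree-capped support
#'
#' Draws a random sparse partial-correlation structure suitable as a
#' recovery-benchmark truth: a near-regular random simple graph with
#' `n_edges` edges whose weights stay inside `weight_range`, with per-node
#' absolute weight budgets (`row_budget`) that keep the unit-diagonal
#' precision matrix comfortably positive definite, so requested and
#' realized weights coincide. A fraction of edges is made negative.
#'
#' @param nodes node labels or a count (default: the 25 subscale acronyms).
#' @param n_edges number of edges (density `n_edges / (k(k-1)/2)`).
#' @param weight_range magnitude range for edge weights.
#' @param prop_negative probability that an edge is negative.
#' @param row_budget maximum absolute off-diagonal row sum of the precision
#'   matrix (< 1 guarantees diagonal dominance, hence PD).
#' @param seed integer seed.
#' @return A `planted_network`.
#' @export
random_planted_network <- function(nodes = psychonectome_nodes(),
                                   n_edges = 45,
                                   weight_range = c(0.2, 0.45),
                                   prop_negative = 0.15,
                                   row_budget = 0.92, seed = 1) {
  if (is.numeric(nodes) && length(nodes) == 1) {
    nodes <- sprintf("V%02d", seq_len(nodes))
  }
  k <- length(nodes)
  if (n_edges > k * (k - 1) / 2) abort("Too many edges for k nodes.")
  withr::with_seed(seed, {
    base <- (2 * n_edges) %/% k
    extra <- 2 * n_edges - base * k
    degrees <- sample(c(rep(base + 1L, extra), rep(base, k - extra)))
    g <- igraph::sample_degseq(degrees, method = "vl")
    el <- igraph::as_edgelist(g)
    allowance <- row_budget / pmax(degrees, 1)
    edges <- lapply(seq_len(nrow(el)), function(e) {
      i <- el[e, 1]
      j <- el[e, 2]
      cap <- max(weight_range[1], min(allowance[i], allowance[j],
                                      weight_range[2]))
      w <- runif(1, weight_range[1], cap)
      if (runif(1) < prop_negative) w <- -w
      list(from = nodes[i], to = nodes[j], weight = w)
    })
    make_planted_network(nodes, negative_edges = edges,
                         description = sprintf(
                           "random planted network: %d edges, |w| in [%.2f, %.2f]",
                           n_edges, weight_range[1], weight_range[2]
                         ))
  })
}
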