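#' Signed spinglass Hamiltonian
#'
#' Evaluates the signed Reichardt-Bornholdt Potts Hamiltonian
#' `H = -sum_{i<j} (w+_ij - gamma * p+_ij) d(s_i, s_j)
#'      + sum_{i<j} (w-_ij - gamma * p-_ij) d(s_i, s_j)`,
#' where `w+`/`w-` are the positive/negative parts of the weights and
#' `p+`/`p-` are configuration-model expectations built from the
#' corresponding signed strength sequences (`p_ij = s_i s_j / (2W)` within
#' each sign layer).
#'
#' @param net a `psy_network`.
#' @param membership named integer vector (or a `psy_partition`) assigning
#'   every node a community.
#' @param gamma resolution parameter.
#' @return The Hamiltonian value (numeric scalar).
#' @export
hamiltonian <- function(net, membership, gamma = 1) {
  if (inherits(membership, "psy_partition")) {
    membership <- setNames(membership$community, membership$node)
  }
  if (!all(net$nodes %in% names(membership))) {
    abort("`membership` must assign every node of the network.")
  }
  sig <- membership[net$nodes]
  A <- rb_coupling(net, gamma)
  same <- outer(sig, sig, "==")
  -sum(A[upper.tri(A)] * same[upper.tri(same)])
}

# Coupling matrix A_ij = (w+ - gamma p+) - (w- - gamma p-); H(sigma) =
# -sum_{i<j} A_ij delta(sigma_i, sigma_j).
rb_coupling <- function(net, gamma) {
  w <- net$weights
  w[abs(w) < EDGE_EPS] <- 0
  null_part <- function(wp) {
    s <- rowSums(wp)
    W2 <- sum(s)
    if (W2 == 0) return(matrix(0, nrow(wp), ncol(wp)))
    p <- tcrossprod(s) / W2
    diag(p) <- 0
    p
  }
  wp <- pmax(w, 0)
  wn <- pmax(-w, 0)
  A <- (wp - gamma * null_part(wp)) - (wn - gamma * null_part(wn))
  diag(A) <- 0
  A
}

#' Spinglass community detection on a signed network
#'
#' Minimizes the signed Reichardt-Bornholdt Hamiltonian (see
#' [hamiltonian()]) by simulated annealing: spins start uniformly at random
#' in `1..spins`; at each temperature `sweeps_per_temp` Metropolis sweeps
#' are performed (one sweep proposes a new random spin for each node in
#' random order), then the temperature is multiplied by `cooling_factor`
#' until it falls below `stop_temp`. The defaults are the annealing
#' settings conventional for questionnaire networks of ~25 nodes:
#' `gamma = 1`, start temperature 1, stop temperature 0.01, cooling factor
#' 0.99, `spins = 25`.
#'
#' @param net a `psy_network` with at least one edge (an edgeless network
#'   returns singleton communities with a warning).
#' @param gamma resolution parameter.
#' @param start_temp,stop_temp,cooling_factor annealing schedule
#'   (`0 < stop_temp < start_temp`, `0 < cooling_factor < 1`).
#' @param spins maximum number of communities (>= 2).
#' @param sweeps_per_temp sweeps per temperature step; default one expected
#'   update per node (`k`).
#' @param restarts best-of-m restarts by final Hamiltonian (seeded
#'   substreams, deterministic).
#' @param seed integer seed.
#' @return A `psy_partition`: tibble with columns `node` and `community`
#'   (consecutive ids from 0), with the final Hamiltonian, the number of
#'   communities and the parameters as attributes.
#' @export
spinglass <- function(net, gamma = 1, start_temp = 1, stop_temp = 0.01,
                      cooling_factor = 0.99, spins = 25,
                      sweeps_per_temp = NULL, restarts = 1, seed = 1) {
  stopifnot(stop_temp > 0, start_temp > stop_temp,
            cooling_factor > 0, cooling_factor < 1, spins >= 2)
  k <- length(net$nodes)
  sweeps_per_temp <- sweeps_per_temp %||% k
  if (network_density(net)$edges == 0) {
    warn("Edgeless network: every node becomes its own community.")
    return(new_psy_partition(net$nodes, seq_len(k) - 1L, 0,
                             params = list(gamma = gamma)))
  }
  A <- rb_coupling(net, gamma)
  seeds <- substream_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- withr::with_seed(seeds[r], anneal_spinglass_cpp(
      A, spins, start_temp, stop_temp, cooling_factor, sweeps_per_temp
    ))
    if (is.null(best) || res$H < best$H) best <- res
  }
  sig <- match(best$sigma, unique(best$sigma)) - 1L
  new_psy_partition(
    net$nodes, sig, best$H,
    params = list(
      gamma = gamma, start_temp = start_temp, stop_temp = stop_temp,
      cooling_factor = cooling_factor, spins = spins,
      sweeps_per_temp = sweeps_per_temp, restarts = restarts, seed = seed
    )
  )
}

new_psy_partition <- function(nodes, community, H, params = list()) {
  out <- tibble(node = nodes, community = as.integer(community))
  structure(
    out,
    hamiltonian = H, n_communities = length(unique(community)),
    params = params,
    class = c("psy_partition", class(out))
  )
}

#' @rdname tidy-psychonectome
#' @export
glance.psy_partition <- function(x, ...) {
  tibble(
    n_communities = attr(x, "n_communities"),
    hamiltonian = attr(x, "hamiltonian"),
    nodes = nrow(x)
  )
}

#' Compare two partitions of the same node set
#'
#' Adjusted Rand index (chance-corrected pair agreement; 1 iff identical up
#' to relabeling) and normalized mutual information.
#'
#' @param p1,p2 `psy_partition`s (or named membership vectors) over the same
#'   nodes.
#' @return A tibble with columns `ari` and `nmi`.
#' @export
compare_partitions <- function(p1, p2) {
  as_member <- function(p) {
    if (inherits(p, "psy_partition")) setNames(p$community, p$node) else p
  }
  m1 <- as_member(p1)
  m2 <- as_member(p2)
  if (!setequal(names(m1), names(m2))) {
    abort("Partitions must cover the same node set.")
  }
  m2 <- m2[names(m1)]
  tibble(
    ari = mclust::adjustedRandIndex(m1, m2),
    nmi = nmi_index(m1, m2)
  )
}

# Normalized mutual information, 2 I(X;Y) / (H(X) + H(Y)). Two partitions
# with zero joint entropy (both trivial) are identical, hence 1.
nmi_index <- function(m1, m2) {
  p <- table(m1, m2) / length(m1)
  pi <- rowSums(p)
  pj <- colSums(p)
  hx <- -sum(pi * log(pi), na.rm = TRUE)
  hy <- -sum(pj * log(pj), na.rm = TRUE)
  if (hx + hy == 0) return(1)
  expected <- tcrossprod(pi, pj)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / expected[nz]))
  2 * mi / (hx + hy)
}

#' Write a partition
#'
#' Two-column CSV (`node`, `community`) plus a JSON sidecar with the
#' annealing parameters and the final Hamiltonian.
#'
#' @param partition a `psy_partition`.
#' @param path CSV file path.
#' @export
write_partition <- function(partition, path) {
  readr::write_csv(as_tibble(partition), path)
  jsonlite::write_json(
    list(params = attr(partition, "params"),
         hamiltonian = attr(partition, "hamiltonian"),
         n_communities = attr(partition, "n_communities")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
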