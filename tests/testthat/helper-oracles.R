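# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive: direct enumeration and
# textbook formulas, sharing no code with the implementation paths they
# check.

# All set partitions of 1..k as membership vectors (restricted growth
# strings); Bell(8) = 4140 so this is fine up to k ~ 10.
enum_partitions <- function(k) {
  out <- list()
  grow <- function(member, maxid) {
    i <- length(member) + 1
    if (i > k) {
      out[[length(out) + 1]] <<- member
      return(invisible())
    }
    for (c in seq_len(maxid + 1)) {
      grow(c(member, c), max(maxid, c))
    }
  }
  grow(integer(0), 0L)
  out
}

# Signed RB Hamiltonian computed straight from the definition.
brute_hamiltonian <- function(w, member, gamma = 1) {
  k <- ncol(w)
  wp <- pmax(w, 0)
  wn <- pmax(-w, 0)
  null_p <- function(m) {
    s <- rowSums(m)
    tw <- sum(s)
    if (tw == 0) matrix(0, k, k) else tcrossprod(s) / tw
  }
  pp <- null_p(wp)
  pn <- null_p(wn)
  H <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (member[i] == member[j]) {
        H <- H - (wp[i, j] - gamma * pp[i, j]) + (wn[i, j] - gamma * pn[i, j])
      }
    }
  }
  H
}

# Same definition as brute_hamiltonian, vectorized over the pair sum so
# exhaustive search over all partitions stays affordable.
brute_min_hamiltonian <- function(w, gamma = 1) {
  k <- ncol(w)
  wp <- pmax(w, 0)
  wn <- pmax(-w, 0)
  null_p <- function(m) {
    s <- rowSums(m)
    tw <- sum(s)
    if (tw == 0) matrix(0, k, k) else tcrossprod(s) / tw
  }
  A <- (wp - gamma * null_p(wp)) - (wn - gamma * null_p(wn))
  diag(A) <- 0
  parts <- enum_partitions(k)
  hs <- vapply(parts, function(m) {
    -sum(A * outer(m, m, "==")) / 2
  }, numeric(1))
  list(H = min(hs), member = parts[[which.min(hs)]])
}

# Onnela weighted clustering by explicit triple enumeration.
brute_clustering <- function(w) {
  w <- abs(w)
  k <- ncol(w)
  wh <- if (max(w) > 0) w / max(w) else w
  d <- rowSums(w > 0)
  out <- numeric(k)
  for (i in seq_len(k)) {
    if (d[i] < 2) next
    tot <- 0
    for (j in seq_len(k)) {
      for (h in seq_len(k)) {
        if (j != i && h != i && j != h &&
            w[i, j] > 0 && w[i, h] > 0 && w[j, h] > 0) {
          tot <- tot + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
        }
      }
    }
    out[i] <- tot / (d[i] * (d[i] - 1))
  }
  out
}

# Global/nodal efficiency via Floyd-Warshall on lengths 1/|w|.
brute_efficiency <- function(w) {
  k <- ncol(w)
  d <- matrix(Inf, k, k)
  diag(d) <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && abs(w[i, j]) > 0) d[i, j] <- 1 / abs(w[i, j])
    }
  }
  for (m in seq_len(k)) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
      }
    }
  }
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  list(global = sum(inv) / (k * (k - 1)), nodal = rowSums(inv) / (k - 1))
}

# Pair-counting adjusted Rand index from the contingency table.
brute_ari <- function(m1, m2) {
  tab <- table(m1, m2)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  a <- sum_comb(tab)
  b <- sum_comb(rowSums(tab))
  cc <- sum_comb(colSums(tab))
  expected <- b * cc / choose(n, 2)
  maxidx <- (b + cc) / 2
  if (maxidx == expected) return(1)
  (a - expected) / (maxidx - expected)
}

# Random signed weighted network for property tests.
random_network <- function(k, density = 0.4, seed = 1, signed = TRUE) {
  withr::with_seed(seed, {
    w <- matrix(0, k, k)
    up <- which(upper.tri(w))
    on <- up[runif(length(up)) < density]
    vals <- runif(length(on), 0.1, 0.6)
    if (signed) vals <- vals * sample(c(-1, 1), length(on), replace = TRUE)
    w[on] <- vals
    w <- w + t(w)
    colnames(w) <- rownames(w) <- sprintf("N%02d", seq_len(k))
    new_psy_network(w)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chain_net <- function(weights, labels = NULL) {
  k <- length(weights) + 1
  labels <- labels %||% LETTERS[seq_len(k)]
  make_planted_network(
    nodes = labels,
    chains = list(list(nodes = labels, weights = weights))
  )
}
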