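# Internal helpers shared across modules.

# Draw B substream seeds from one master seed so replicate b is reproducible
# independently of how replicates are scheduled across workers.
substream_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_square_symmetric <- function(m, what = "matrix", tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", what))
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("`%s` must be symmetric.", what))
  }
  invisible(m)
}

# Smallest ridge delta such that min eigenvalue of m + delta*I >= floor.
# Eigenvalues shift linearly in delta, so the binary-search limit has the
# closed form max(0, floor - min_eig).
ridge_to_pd <- function(m, floor = 1e-6) {
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  max(0, floor - ev)
}

upper_pairs <- function(labels) {
  k <- length(labels)
  idx <- which(upper.tri(diag(k)), arr.ind = TRUE)
  tibble(
    from = labels[idx[, 1]],
    to = labels[idx[, 2]],
    i = idx[, 1],
    j = idx[, 2]
  )
}

# Rank-based inverse-normal transform with the Blom offset; mid-ranks for
# ties. NAs are ranked among observed values only and returned as NA.
blom_scores <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  out <- rep(NA_real_, length(x))
  r <- rank(x[obs], ties.method = "average")
  out[obs] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}
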