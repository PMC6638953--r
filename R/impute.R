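#' Expectation-maximization imputation of a cohort
#'
#' Scores are first mapped column-wise to rank-based normal scores (Blom
#' offset, mid-ranks for ties), a multivariate-normal EM is run on the
#' incomplete score matrix until the relative observed-data log-likelihood
#' change drops below `tol` (default 1e-6) or `max_iter` iterations, and the
#' conditional means of the missing entries are back-transformed onto each
#' column's observed grid (nearest observed category for ordinal cohorts,
#' empirical-quantile interpolation for continuous ones). Observed entries
#' are returned unchanged.
#'
#' @param cohort a `psy_cohort` with less than 50% missingness and at least
#'   10 rows that are at least half observed.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return A complete `psy_cohort`; attribute `"em"` records iterations,
#'   convergence and the final log-likelihood. Columns with zero observed
#'   variance are dropped with a warning.
#' @export
em_impute <- function(cohort, max_iter = 100, tol = 1e-6) {
  m <- cohort_scores(cohort)
  if (!anyNA(m)) return(cohort)
  if (mean(is.na(m)) >= 0.5) abort("Overall missingness must be below 50%.")
  if (sum(rowMeans(!is.na(m)) >= 0.5) < 10) {
    abort("Need at least 10 rows with at least half their entries observed.")
  }
  sds <- apply(m, 2, sd, na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warn(sprintf("Dropping zero-variance column(s): %s",
                 paste(colnames(m)[drop], collapse = ", ")))
    m <- m[, !drop, drop = FALSE]
  }

  z <- apply(m, 2, blom_scores)
  fit <- mvn_em(z, max_iter = max_iter, tol = tol)

  # back-transform imputed normal scores onto each column's observed grid
  filled <- m
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (!any(miss)) next
    obs_x <- m[!miss, j]
    obs_z <- z[!miss, j]
    map <- dplyr::distinct(tibble(x = obs_x, z = obs_z)) |> arrange(.data$z)
    zj <- fit$z[miss, j]
    if (cohort_levels(cohort) > 0) {
      filled[miss, j] <- map$x[
        vapply(zj, function(v) which.min(abs(map$z - v)), integer(1))
      ]
    } else {
      filled[miss, j] <- stats::approx(map$z, map$x, xout = zj, rule = 2)$y
    }
  }

  out <- cohort[, c("subject_id", colnames(filled))]
  out[, colnames(filled)] <- as.data.frame(filled)
  attr(out, "occasion") <- cohort_occasion(cohort)
  attr(out, "levels") <- cohort_levels(cohort)
  attr(out, "latent") <- attr(cohort, "latent")
  attr(out, "em") <- fit[c("iterations", "converged", "loglik")]
  class(out) <- class(cohort)
  out
}

# Multivariate-normal EM on an incomplete matrix. Returns the data with
# missing entries replaced by conditional means, plus mu/Sigma and the
# observed-data log-likelihood trace.
mvn_em <- function(z, max_iter = 100, tol = 1e-6) {
  n <- nrow(z)
  p <- ncol(z)
  miss <- is.na(z)
  mu <- colMeans(z, na.rm = TRUE)
  S <- cov(z, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  S <- S + ridge_to_pd(S, 1e-4) * diag(p)

  pattern <- apply(miss, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), pattern)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0
  zfill <- z
  repeat {
    it <- it + 1
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    ll <- 0
    for (g in groups) {
      mi <- which(miss[g[1], ])
      oi <- setdiff(seq_len(p), mi)
      zg <- z[g, , drop = FALSE]
      ng <- length(g)
      if (length(oi)) {
        Soo <- S[oi, oi, drop = FALSE]
        ll <- ll + sum(mvtnorm::dmvnorm(
          zg[, oi, drop = FALSE], mean = mu[oi], sigma = Soo, log = TRUE
        ))
      }
      if (length(mi)) {
        if (length(oi)) {
          A <- S[mi, oi, drop = FALSE] %*% solve(S[oi, oi, drop = FALSE])
          cond_mean <- matrix(mu[mi], ng, length(mi), byrow = TRUE) +
            sweep(zg[, oi, drop = FALSE], 2, mu[oi]) %*% t(A)
          cond_var <- S[mi, mi, drop = FALSE] -
            A %*% t(S[mi, oi, drop = FALSE])
        } else {
          cond_mean <- matrix(mu[mi], ng, length(mi), byrow = TRUE)
          cond_var <- S[mi, mi, drop = FALSE]
        }
        zg[, mi] <- cond_mean
        sum_xx[mi, mi] <- sum_xx[mi, mi] + ng * cond_var
        zfill[g, mi] <- cond_mean
      }
      sum_x <- sum_x + colSums(zg)
      sum_xx <- sum_xx + crossprod(zg)
    }
    mu_new <- sum_x / n
    S_new <- sum_xx / n - tcrossprod(mu_new)
    S_new <- (S_new + t(S_new)) / 2
    S_new <- S_new + ridge_to_pd(S_new, 1e-8) * diag(p)
    mu <- mu_new
    S <- S_new
    if (is.finite(ll_old) && abs(ll - ll_old) / (abs(ll_old) + 1e-12) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
  }
  if (!converged) {
    warn(sprintf("EM did not converge in %d iterations; best iterate used.",
                 max_iter))
  }
  # final E-step fill with the converged parameters
  for (g in groups) {
    mi <- which(miss[g[1], ])
    oi <- setdiff(seq_len(p), mi)
    if (!length(mi)) next
    if (length(oi)) {
      A <- S[mi, oi, drop = FALSE] %*% solve(S[oi, oi, drop = FALSE])
      zfill[g, mi] <- matrix(mu[mi], length(g), length(mi), byrow = TRUE) +
        sweep(z[g, oi, drop = FALSE], 2, mu[oi]) %*% t(A)
    } else {
      zfill[g, mi] <- matrix(mu[mi], length(g), length(mi), byrow = TRUE)
    }
  }
  list(z = zfill, mu = mu, sigma = S, iterations = it, converged = converged,
       loglik = ll)
}
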