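#' Correlation-matrix objects
#'
#' A `psy_corr` wraps a symmetric unit-diagonal correlation matrix together
#' with the estimation method (`"spearman"`, `"polychoric"`, `"pearson"`),
#' the per-pair effective sample sizes, and a flag recording whether a
#' positive-semidefiniteness repair (eigenvalue clipping) was applied.
#'
#' @param values symmetric correlation matrix with dimnames.
#' @param method estimation method label.
#' @param n_effective matrix of per-pair complete-case counts.
#' @param repaired logical: was the PSD repair triggered?
#' @return A `psy_corr` object.
#' @export
new_psy_corr <- function(values, method, n_effective = NULL,
                         repaired = FALSE) {
  check_square_symmetric(values, "values", tol = 1e-8)
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(
    list(values = values, method = method, n_effective = n_effective,
         repaired = repaired),
    class = "psy_corr"
  )
}

#' @export
print.psy_corr <- function(x, ...) {
  cat(sprintf("<psy_corr> %s, %d nodes%s\n", x$method, ncol(x$values),
              if (x$repaired) " (PSD-repaired)" else ""))
  invisible(x)
}

#' @rdname tidy-psychonectome
#' @export
tidy.psy_corr <- function(x, ...) {
  up <- upper_pairs(colnames(x$values))
  up |>
    mutate(
      correlation = x$values[cbind(up$i, up$j)],
      n = if (is.null(x$n_effective)) NA_integer_
          else x$n_effective[cbind(up$i, up$j)]
    ) |>
    select("from", "to", "correlation", "n")
}

# Clip negative eigenvalues at zero and re-standardize to unit diagonal.
psd_repair <- function(m, tol = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    return(list(values = m, repaired = FALSE))
  }
  v <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  v <- stats::cov2cor(v)
  dimnames(v) <- dimnames(m)
  list(values = (v + t(v)) / 2, repaired = TRUE)
}

#' Spearman correlation matrix of a cohort
#'
#' Mid-rank Spearman correlations computed on pairwise-complete cases. If
#' the resulting matrix is not positive semidefinite it is projected to the
#' nearest PSD correlation matrix (negative eigenvalues clipped at zero,
#' then re-standardized) and the repair is flagged.
#'
#' @param cohort a `psy_cohort` (or data frame accepted by [as_cohort()]).
#' @return A `psy_corr` with `method = "spearman"`.
#' @export
spearman_matrix <- function(cohort) {
  m <- cohort_scores(cohort)
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    bad <- colnames(m)[which(is.na(sds) | sds == 0)]
    abort(sprintf("Constant column(s): %s — Spearman undefined.",
                  paste(bad, collapse = ", ")))
  }
  n_eff <- crossprod(!is.na(m))
  if (any(n_eff[upper.tri(n_eff)] < 3)) {
    abort("Every node pair needs at least 3 complete cases.")
  }
  r <- cor(m, method = "spearman", use = "pairwise.complete.obs")
  rep <- psd_repair(r)
  new_psy_corr(rep$values, "spearman", n_eff, rep$repaired)
}

#' Polychoric correlation matrix of an ordinal cohort
#'
#' Two-step pairwise estimator: thresholds are fixed from each margin's
#' cumulative observed proportions through the standard normal quantile,
#' then the latent correlation of each pair maximizes the bivariate-normal
#' cell likelihood over (-0.999, 0.999) with a bounded scalar optimizer
#' (tolerance 1e-6). Non-PSD results are repaired as in
#' [spearman_matrix()].
#'
#' @param cohort a `psy_cohort` with 2-10 observed categories per column.
#' @return A `psy_corr` with `method = "polychoric"`.
#' @export
polychoric_matrix <- function(cohort) {
  m <- cohort_scores(cohort)
  k <- ncol(m)
  cats <- lapply(seq_len(k), function(j) sort(unique(m[!is.na(m[, j]), j])))
  nc <- lengths(cats)
  if (any(nc < 2)) {
    abort(sprintf("Column(s) with a single observed category: %s.",
                  paste(colnames(m)[nc < 2], collapse = ", ")))
  }
  if (any(nc > 10)) {
    abort("Polychoric estimation expects at most 10 observed categories.")
  }
  # thresholds per margin from marginal cumulative proportions
  thr <- lapply(seq_len(k), function(j) {
    x <- m[!is.na(m[, j]), j]
    p <- cumsum(tabulate(match(x, cats[[j]]))) / length(x)
    qnorm(p[-length(p)])
  })
  n_eff <- crossprod(!is.na(m))
  r <- diag(k)
  dimnames(r) <- dimnames(n_eff) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      ok <- complete.cases(m[, c(i, j)])
      tab <- table(
        factor(m[ok, i], levels = cats[[i]]),
        factor(m[ok, j], levels = cats[[j]])
      )
      r[i, j] <- r[j, i] <- polychoric_rho(tab, thr[[i]], thr[[j]])
    }
  }
  rep <- psd_repair(r)
  new_psy_corr(rep$values, "polychoric", n_eff, rep$repaired)
}

# Bivariate normal CDF at (h, k) with correlation rho; +/-Inf supported.
biv_phi <- function(h, k, rho) {
  if (is.infinite(h) && h < 0) return(0)
  if (is.infinite(k) && k < 0) return(0)
  if (is.infinite(h)) return(pnorm(k))
  if (is.infinite(k)) return(pnorm(h))
  mvtnorm::pmvnorm(
    upper = c(h, k),
    corr = matrix(c(1, rho, rho, 1), 2)
  )[1]
}

polychoric_rho <- function(tab, a, b) {
  ab <- c(-Inf, a, Inf)
  bb <- c(-Inf, b, Inf)
  nr <- length(ab) - 1
  nc <- length(bb) - 1
  negll <- function(rho) {
    corner <- outer(seq_len(nr + 1), seq_len(nc + 1),
                    Vectorize(function(i, j) biv_phi(ab[i] - 0, bb[j] - 0, rho)))
    # corner[i, j] = Phi2(ab[i], bb[j]); cell probs by inclusion-exclusion
    p <- corner[-1, -1] - corner[-(nr + 1), -1] -
      corner[-1, -(nc + 1)] + corner[-(nr + 1), -(nc + 1)]
    p <- pmax(p, 1e-12)
    -sum(tab * log(p))
  }
  optimize(negll, c(-0.999, 0.999), tol = 1e-6)$minimum
}

#' Standardized Cronbach's alpha from a correlation matrix
#'
#' `alpha = k * rbar / (1 + (k - 1) * rbar)` where `rbar` is the mean
#' inter-item correlation over the chosen subset. Computed on polychoric
#' correlations this gives the ordinal internal-consistency coefficient.
#'
#' @param corr a `psy_corr` (or bare correlation matrix).
#' @param items character or integer subset of at least 2 items; defaults to
#'   all.
#' @return A single numeric alpha.
#' @export
cronbach_alpha <- function(corr, items = NULL) {
  v <- if (inherits(corr, "psy_corr")) corr$values else corr
  if (!is.null(items)) v <- v[items, items, drop = FALSE]
  kk <- ncol(v)
  if (kk < 2) abort("Cronbach's alpha needs at least 2 items.")
  rbar <- mean(v[upper.tri(v)])
  if (rbar <= -1 / (kk - 1)) {
    abort(sprintf(
      "Mean inter-item correlation %.3f <= -1/(k-1); alpha undefined.", rbar
    ))
  }
  kk * rbar / (1 + (kk - 1) * rbar)
}

#' Write / read a correlation matrix
#'
#' CSV with a header row and a leading label column, plus a JSON sidecar
#' (`<path>.json`) recording method, repair flag and per-pair sample sizes.
#'
#' @param corr a `psy_corr`.
#' @param path CSV file path.
#' @export
write_correlation <- function(corr, path) {
  df <- as.data.frame(corr$values)
  readr::write_csv(tibble(node = rownames(corr$values), !!!df), path)
  jsonlite::write_json(
    list(method = corr$method, repaired = corr$repaired,
         n_effective = corr$n_effective),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  v <- as.matrix(df[, -1])
  rownames(v) <- df$node
  n_eff <- if (!is.null(side$n_effective)) as.matrix(side$n_effective)
  new_psy_corr(v, side$method, n_eff, side$repaired)
}
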