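#' Node predictability
#'
#' For each node, the proportion of variance explained (R-squared) by a
#' least-squares regression of its normal scores on the normal scores of
#' all other nodes — an absolute measure of how interconnected the node is.
#' Values are clipped to \[0, 1\].
#'
#' @param cohort a complete `psy_cohort` (impute first) with `k <= n - 2`.
#' @return A tibble of class `psy_predictability` with columns `node` and
#'   `r_squared`; the network mean is available via [generics::glance()]
#'   and the `"mean_r_squared"` attribute.
#' @export
predictability <- function(cohort) {
  z <- normal_scores(cohort)
  n <- nrow(z)
  k <- ncol(z)
  if (k > n - 2) abort("Saturated regression: need k <= n - 2.")
  r2 <- vapply(seq_len(k), function(j) {
    fit <- stats::lm.fit(cbind(1, z[, -j, drop = FALSE]), z[, j])
    1 - sum(fit$residuals^2) / sum((z[, j] - mean(z[, j]))^2)
  }, numeric(1))
  r2 <- pmin(pmax(r2, 0), 1)
  out <- tibble(node = colnames(z), r_squared = r2)
  structure(
    out, mean_r_squared = mean(r2), scores = "rank-based normal (Gaussian)",
    class = c("psy_predictability", class(out))
  )
}

#' @rdname tidy-psychonectome
#' @export
glance.psy_predictability <- function(x, ...) {
  tibble(mean_r_squared = attr(x, "mean_r_squared"), nodes = nrow(x))
}

#' Bootstrap edge-weight accuracy
#'
#' Nonparametric bootstrap: subjects are resampled with replacement and the
#' full estimation pipeline (normal scores, nodewise adaptive-LASSO GGM) is
#' re-run on every replicate. Per edge, the 2.5 and 97.5 percentiles of the
#' replicate weights give a 95% interval around the full-sample point
#' estimate (the interval is widened to contain the point estimate if a
#' percentile falls inside it). Replicates are driven by indexed seed
#' substreams, so results do not depend on execution order.
#'
#' @param cohort a complete `psy_cohort`.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer master seed.
#' @param folds,rule,screening,n_lambda,lambda_min_ratio passed to
#'   [estimate_network()].
#' @param level interval coverage (default 0.95).
#' @return A tibble of class `psy_edge_ci` with columns `from`, `to`,
#'   `lower`, `point`, `upper`, `prop_nonzero`.
#' @export
bootstrap_edges <- function(cohort, B = 1000, seed = 1, folds = 10,
                            rule = "and", screening = "1se", n_lambda = 50,
                            lambda_min_ratio = 1e-4, level = 0.95) {
  if (B < 100) abort("`B` must be at least 100.")
  z <- normal_scores(cohort)
  n <- nrow(z)
  point_net <- estimate_network(z, folds = folds, seed = seed, rule = rule,
                                screening = screening, n_lambda = n_lambda,
                                lambda_min_ratio = lambda_min_ratio)
  up <- upper_pairs(colnames(z))
  seeds <- substream_seeds(seed, B)
  reps <- matrix(NA_real_, B, nrow(up))
  redraws <- 0L
  for (b in seq_len(B)) {
    sb <- seeds[b]
    for (try in 0:10) {
      idx <- withr::with_seed(sb + try, sample.int(n, n, replace = TRUE))
      zb <- z[idx, , drop = FALSE]
      if (all(apply(zb, 2, sd) > 0)) break
      redraws <- redraws + 1L
      if (try == 10) abort("Replicate kept drawing constant columns.")
    }
    netb <- estimate_network(zb, folds = folds, seed = sb, rule = rule,
                             screening = screening, n_lambda = n_lambda,
                             lambda_min_ratio = lambda_min_ratio)
    reps[b, ] <- netb$weights[cbind(up$i, up$j)]
  }
  alpha <- (1 - level) / 2
  point <- point_net$weights[cbind(up$i, up$j)]
  lo <- apply(reps, 2, quantile, probs = alpha, names = FALSE)
  hi <- apply(reps, 2, quantile, probs = 1 - alpha, names = FALSE)
  out <- tibble(
    from = up$from, to = up$to,
    lower = pmin(lo, point), point = point, upper = pmax(hi, point),
    prop_nonzero = colMeans(abs(reps) >= EDGE_EPS)
  )
  structure(out, B = B, seed = seed, level = level, redraws = redraws,
            network = point_net,
            class = c("psy_edge_ci", class(out)))
}

#' Case-dropping stability of centrality indices
#'
#' For each drop proportion `p`, draws `B` subsamples without replacement
#' of size `ceiling(n * (1 - p))`, re-runs the full estimation, and
#' correlates each centrality vector with its full-sample counterpart. The
#' CS-coefficient of an index is the largest `p` whose correlation stays at
#' or above `cor_threshold` in at least `assurance` of the subsamples (0 if
#' none).
#'
#' @param cohort a complete `psy_cohort`.
#' @param proportions drop proportions in (0, 0.75\]; proportions whose
#'   retained subsample would fall below `k + 10` rows are skipped with a
#'   warning.
#' @param B subsamples per proportion.
#' @param indices centrality indices to track (columns of
#'   [centrality_table()]).
#' @param seed integer master seed.
#' @param cor_threshold,assurance CS-coefficient convention (defaults 0.7
#'   and 0.95).
#' @param folds passed to [estimate_network()].
#' @return A list of class `psy_stability`: `curves` (tibble: proportion,
#'   index, mean_correlation, q05, prop_above) and `cs` (tibble: index,
#'   cs_coefficient).
#' @export
case_drop_stability <- function(cohort,
                                proportions = seq(0.05, 0.75, by = 0.05),
                                B = 500,
                                indices = c("expected_influence", "strength"),
                                seed = 1, cor_threshold = 0.7,
                                assurance = 0.95, folds = 10) {
  z <- normal_scores(cohort)
  n <- nrow(z)
  k <- ncol(z)
  full <- centrality_table(estimate_network(z, folds = folds, seed = seed))
  keep <- ceiling(n * (1 - proportions)) >= k + 10
  if (any(!keep)) {
    warn(sprintf("Skipping proportions with retained n < k + 10: %s",
                 paste(proportions[!keep], collapse = ", ")))
    proportions <- proportions[keep]
  }
  grid <- tidyr::expand_grid(proportion = proportions, b = seq_len(B))
  seeds <- substream_seeds(seed, nrow(grid))
  cors <- matrix(NA_real_, nrow(grid), length(indices))
  colnames(cors) <- indices
  for (g in seq_len(nrow(grid))) {
    p <- grid$proportion[g]
    m <- ceiling(n * (1 - p))
    if (m == n) {
      # dropping nobody reproduces the full-sample estimate exactly
      cors[g, ] <- 1
      next
    }
    idx <- withr::with_seed(seeds[g], sample.int(n, m))
    zs <- z[idx, , drop = FALSE]
    if (any(apply(zs, 2, sd) == 0)) next
    tab <- centrality_table(estimate_network(zs, folds = folds,
                                             seed = seeds[g]))
    for (ix in indices) {
      a <- full[[ix]]
      bvec <- tab[[ix]]
      if (sd(a) > 0 && sd(bvec) > 0) {
        cors[g, ix] <- cor(a, bvec)
      }
    }
  }
  curves <- bind_rows(lapply(indices, function(ix) {
    tibble(proportion = grid$proportion, correlation = cors[, ix],
           index = ix)
  })) |>
    group_by(.data$index, .data$proportion) |>
    summarise(
      mean_correlation = mean(.data$correlation, na.rm = TRUE),
      q05 = quantile(.data$correlation, 0.05, na.rm = TRUE, names = FALSE),
      # a degenerate centrality vector (e.g. an empty estimated network)
      # gives an undefined correlation: counted as not stable
      prop_above = mean(!is.na(.data$correlation) &
                          .data$correlation >= cor_threshold),
      .groups = "drop"
    )
  cs <- curves |>
    group_by(.data$index) |>
    summarise(
      cs_coefficient = {
        ok <- !is.na(.data$prop_above) & .data$prop_above >= assurance
        if (any(ok)) max(.data$proportion[ok]) else 0
      },
      .groups = "drop"
    )
  structure(
    list(curves = curves, cs = cs, full = full),
    B = B, seed = seed, cor_threshold = cor_threshold,
    assurance = assurance,
    class = "psy_stability"
  )
}

#' @export
print.psy_stability <- function(x, ...) {
  cat("<psy_stability> case-dropping curves\n")
  print(x$cs)
  invisible(x)
}

#' Write a stability report
#'
#' Curves as CSV (`proportion`, `index`, `mean_correlation`, `q05`,
#' `prop_above`) and CS-coefficients in a JSON sidecar.
#'
#' @param stab a `psy_stability`.
#' @param path CSV path for the curves.
#' @export
write_stability <- function(stab, path) {
  readr::write_csv(stab$curves, path)
  jsonlite::write_json(
    list(cs = stab$cs, B = attr(stab, "B"), seed = attr(stab, "seed"),
         cor_threshold = attr(stab, "cor_threshold"),
         assurance = attr(stab, "assurance")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write bootstrap edge intervals
#'
#' TSV with columns `node_i`, `node_j`, `lower`, `point`, `upper`.
#'
#' @param ci a `psy_edge_ci`.
#' @param path TSV path.
#' @export
write_edge_ci <- function(ci, path) {
  readr::write_tsv(
    setNames(as_tibble(ci)[, c("from", "to", "lower", "point", "upper")],
             c("node_i", "node_j", "lower", "point", "upper")),
    path
  )
  invisible(path)
}
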