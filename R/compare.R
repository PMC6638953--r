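#' Paired pre/post t-tests per node
#'
#' Student t-tests on raw subscale scores (not normal scores):
#' `t = dbar / (s_d / sqrt(n))` with `df = n_paired - 1`, two-sided p.
#' Subjects are matched on `subject_id`; only subjects present on both
#' occasions enter. Zero-variance differences are flagged (`t` is `NA`).
#'
#' @param pre_cohort,post_cohort cohorts with matching subject ids and node
#'   columns (`n_paired >= 3`).
#' @param adjust p-value adjustment method (default `"none"`, matching
#'   per-test reporting; `"holm"` available).
#' @return A tibble with per-node pre/post means and SDs, `t`, `df`, `p`,
#'   and `flag` for degenerate differences.
#' @export
paired_t <- function(pre_cohort, post_cohort, adjust = "none") {
  nodes <- cohort_nodes(pre_cohort)
  if (!setequal(nodes, cohort_nodes(post_cohort))) {
    abort("Cohorts must share the same node columns.")
  }
  ids <- intersect(pre_cohort$subject_id, post_cohort$subject_id)
  if (length(ids) < 3) abort("Need at least 3 paired subjects.")
  pre <- cohort_scores(pre_cohort)[match(ids, pre_cohort$subject_id), nodes,
                                   drop = FALSE]
  post <- cohort_scores(post_cohort)[match(ids, post_cohort$subject_id),
                                     nodes, drop = FALSE]
  n <- length(ids)
  res <- purrr::map(nodes, function(nd) {
    d <- post[, nd] - pre[, nd]
    ok <- !is.na(d)
    nn <- sum(ok)
    sdd <- sd(d[ok])
    tt <- if (nn >= 2 && sdd > 0) mean(d[ok]) / (sdd / sqrt(nn)) else NA_real_
    tibble(
      node = nd,
      pre_mean = mean(pre[ok, nd]), pre_sd = sd(pre[ok, nd]),
      post_mean = mean(post[ok, nd]), post_sd = sd(post[ok, nd]),
      t = tt, df = nn - 1,
      p = if (is.na(tt)) NA_real_ else 2 * pt(-abs(tt), nn - 1),
      flag = if (is.na(tt)) "zero-variance differences" else NA_character_
    )
  })
  out <- bind_rows(res)
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Per-node centrality change between layers
#'
#' Deltas are `post - pre` for every index shared by the two centrality
#' tables; the top movers are the five nodes with the largest absolute
#' delta per index.
#'
#' @param pre_table,post_table [centrality_table()]s over the same nodes.
#' @return A list with `deltas` (tibble, one row per node) and `top_movers`
#'   (tibble: index, rank, node, delta).
#' @export
centrality_change <- function(pre_table, post_table) {
  if (!setequal(pre_table$node, post_table$node)) {
    abort("Centrality tables must cover the same node set.")
  }
  idx <- setdiff(intersect(names(pre_table), names(post_table)), "node")
  post <- post_table[match(pre_table$node, post_table$node), ]
  deltas <- tibble(node = pre_table$node)
  for (ix in idx) deltas[[ix]] <- post[[ix]] - pre_table[[ix]]
  top <- bind_rows(lapply(idx, function(ix) {
    ord <- order(-abs(deltas[[ix]]))
    head_n <- head(ord, 5)
    tibble(index = ix, rank = seq_along(head_n),
           node = deltas$node[head_n], delta = deltas[[ix]][head_n])
  }))
  list(deltas = deltas, top_movers = top)
}

#' Cross-layer correlations of edges and centralities
#'
#' Pearson correlation of (a) the vectorized upper-triangle edge weights of
#' the two layers and (b) each centrality index across nodes. Low values
#' indicate network reorganization between occasions.
#'
#' @param pre_net,post_net `psy_network`s over the same nodes.
#' @param pre_table,post_table optional matching [centrality_table()]s
#'   (computed from the networks when omitted).
#' @return A tibble with columns `quantity` and `correlation` (`NA` with a
#'   flag when a vector has zero variance).
#' @export
layer_correlation <- function(pre_net, post_net,
                              pre_table = NULL, post_table = NULL) {
  if (!setequal(pre_net$nodes, post_net$nodes)) {
    abort("Networks must share the same node set.")
  }
  wpre <- pre_net$weights[upper.tri(pre_net$weights)]
  pw <- post_net$weights[pre_net$nodes, pre_net$nodes]
  wpost <- pw[upper.tri(pw)]
  pre_table <- pre_table %||% centrality_table(pre_net)
  post_table <- post_table %||% centrality_table(post_net)
  post_table <- post_table[match(pre_table$node, post_table$node), ]
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }
  idx <- setdiff(intersect(names(pre_table), names(post_table)), "node")
  rows <- c(
    list(tibble(quantity = "edge_weights",
                correlation = safe_cor(wpre, wpost))),
    lapply(idx, function(ix) {
      tibble(quantity = ix,
             correlation = safe_cor(pre_table[[ix]], post_table[[ix]]))
    })
  )
  out <- bind_rows(rows)
  out$flag <- ifelse(is.na(out$correlation), "zero-variance vector",
                     NA_character_)
  out
}

#' Full pre/post comparison report
#'
#' Bundles [paired_t()], [centrality_change()], [layer_correlation()] and
#' the partition agreement ([compare_partitions()]) into one object.
#'
#' @param pre_cohort,post_cohort paired cohorts (raw scores, used by the
#'   t-tests).
#' @param pre_net,post_net estimated networks for the two occasions.
#' @param pre_partition,post_partition optional spinglass partitions.
#' @param adjust passed to [paired_t()].
#' @return A list of class `psy_prepost` with elements `tests`, `deltas`,
#'   `top_movers`, `layer_correlations`, `partition_agreement`.
#' @export
compare_pre_post <- function(pre_cohort, post_cohort, pre_net, post_net,
                             pre_partition = NULL, post_partition = NULL,
                             adjust = "none") {
  pre_tab <- centrality_table(pre_net)
  post_tab <- centrality_table(post_net)
  ch <- centrality_change(pre_tab, post_tab)
  agree <- if (!is.null(pre_partition) && !is.null(post_partition)) {
    compare_partitions(pre_partition, post_partition)
  }
  structure(
    list(
      tests = paired_t(pre_cohort, post_cohort, adjust = adjust),
      deltas = ch$deltas,
      top_movers = ch$top_movers,
      layer_correlations = layer_correlation(pre_net, post_net,
                                             pre_tab, post_tab),
      partition_agreement = agree
    ),
    class = "psy_prepost"
  )
}

#' @export
print.psy_prepost <- function(x, ...) {
  cat("<psy_prepost> paired tests:\n")
  print(x$tests, n = 5)
  cat("layer correlations:\n")
  print(x$layer_correlations)
  invisible(x)
}
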