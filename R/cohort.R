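#' Cohort tables
#'
#' A cohort is a tibble with a `subject_id` column followed by one numeric
#' column per node (subscale). Ordinal cohorts hold integer scores in
#' `1..levels`; continuous cohorts (`levels = 0`) hold real values. Missing
#' entries are `NA`. Occasion (`"pre"`, `"post"`, or other) and the number
#' of Likert levels travel as attributes.
#'
#' @param x a data frame with a `subject_id` column and numeric node columns
#'   (a bare matrix is also accepted).
#' @param occasion occasion tag, usually `"pre"` or `"post"`.
#' @param levels number of Likert points (`0` for continuous scores).
#' @return A `psy_cohort` tibble.
#' @export
as_cohort <- function(x, occasion = "pre", levels = 5) {
  if (is.matrix(x)) {
    labs <- colnames(x) %||% sprintf("V%02d", seq_len(ncol(x)))
    x <- as_tibble(as.data.frame(x, col.names = labs))
    x <- tibble(subject_id = sprintf("S%04d", seq_len(nrow(x))), !!!x)
  }
  x <- as_tibble(x)
  if (!"subject_id" %in% names(x)) {
    x <- tibble(subject_id = sprintf("S%04d", seq_len(nrow(x))), !!!x)
  }
  x$subject_id <- as.character(x$subject_id)
  node_cols <- setdiff(names(x), "subject_id")
  if (!length(node_cols)) abort("A cohort needs at least one node column.")
  if (!all(vapply(x[node_cols], is.numeric, logical(1)))) {
    abort("All node columns must be numeric.")
  }
  validate_levels(x[node_cols], levels)
  structure(
    x[, c("subject_id", node_cols)],
    occasion = occasion, levels = levels,
    class = c("psy_cohort", class(as_tibble(x)))
  )
}

validate_levels <- function(df, levels) {
  if (levels > 0) {
    v <- unlist(df, use.names = FALSE)
    v <- v[!is.na(v)]
    if (length(v) && (any(v != round(v)) || any(v < 1) || any(v > levels))) {
      abort(sprintf("Ordinal scores must be integers in [1, %d].", levels))
    }
  }
  invisible(df)
}

#' @export
print.psy_cohort <- function(x, ...) {
  cat(sprintf(
    "<psy_cohort> occasion=%s, levels=%d, %d subjects x %d nodes, %.1f%% missing\n",
    attr(x, "occasion"), attr(x, "levels"),
    nrow(x), ncol(x) - 1L,
    100 * mean(is.na(cohort_scores(x)))
  ))
  NextMethod()
}

#' Extract the score matrix of a cohort
#'
#' @param cohort a `psy_cohort`.
#' @return Numeric matrix (subjects x nodes) with subject ids as row names.
#' @export
cohort_scores <- function(cohort) {
  m <- as.matrix(cohort[, setdiff(names(cohort), "subject_id")])
  rownames(m) <- cohort$subject_id
  m
}

#' @rdname cohort_scores
#' @export
cohort_nodes <- function(cohort) setdiff(names(cohort), "subject_id")

#' @rdname cohort_scores
#' @export
cohort_occasion <- function(cohort) attr(cohort, "occasion") %||% "pre"

#' @rdname cohort_scores
#' @export
cohort_levels <- function(cohort) attr(cohort, "levels") %||% 0

#' Mask cohort entries completely at random
#'
#' Each score cell is set to missing independently with probability `rate`,
#' irrespective of its value (MCAR). The default rate matches the overall
#' missingness the pipeline is designed around (10.8%).
#'
#' @param cohort a `psy_cohort`.
#' @param rate missingness probability in \[0, 0.5\].
#' @param seed integer seed; the mask is deterministic given the seed.
#' @return The cohort with masked entries set to `NA`.
#' @export
apply_mcar <- function(cohort, rate = 0.108, seed = 1) {
  if (!is.numeric(rate) || rate < 0 || rate > 0.5) {
    abort("`rate` must lie in [0, 0.5].")
  }
  m <- cohort_scores(cohort)
  mask <- withr::with_seed(
    seed, matrix(runif(length(m)) < rate, nrow(m), ncol(m))
  )
  m[mask] <- NA
  out <- cohort
  out[, cohort_nodes(cohort)] <- as.data.frame(m)
  out
}

#' Write / read a cohort
#'
#' Writes the score table as CSV (header = node labels, one row per subject,
#' empty cell = missing) plus a JSON sidecar (`<path>.json`) with occasion,
#' levels, and any provenance fields supplied through `extra`.
#'
#' @param cohort a `psy_cohort`.
#' @param path CSV file path.
#' @param extra named list merged into the sidecar.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `psy_cohort`.
#' @export
write_cohort <- function(cohort, path, extra = list()) {
  readr::write_csv(as_tibble(cohort), path, na = "")
  side <- c(
    list(occasion = cohort_occasion(cohort), levels = cohort_levels(cohort)),
    extra
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, na = "")
  as_cohort(df, occasion = side$occasion, levels = as.numeric(side$levels))
}
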