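#' Sample a synthetic cohort from a planted network
#'
#' Draws latent multivariate-normal vectors with the correlation matrix
#' implied by the planted precision structure, then (for `levels > 0`)
#' discretizes each margin into `levels` ordinal categories. With the
#' default equal-probability thresholds every category is equally likely;
#' skewed margins can be requested via `thresholds`.
#'
#' The latent draws are kept on the result as the `"latent"` attribute so
#' imputation-recovery experiments can compare imputed scores with the true
#' underlying values.
#'
#' @param net a [make_planted_network()] object.
#' @param n number of subjects (>= 2).
#' @param levels Likert points (`0` keeps the continuous latent scores).
#' @param occasion occasion tag stored on the cohort.
#' @param thresholds optional vector of `levels - 1` increasing standard
#'   normal cut points, recycled across margins, overriding the
#'   equal-probability default.
#' @param seed integer seed; draws are deterministic given the seed.
#' @return A `psy_cohort` of `n` subjects by `length(net$nodes)` nodes.
#' @export
#' @examples
#' net <- make_planted_network(
#'   nodes = c("A", "B"),
#'   chains = list(list(nodes = c("A", "B"), weights = 0.5))
#' )
#' coh <- sample_cohort(net, n = 100, levels = 5, seed = 1)
sample_cohort <- function(net, n, levels = 5, occasion = "pre",
                          thresholds = NULL, seed = 1) {
  stopifnot(inherits(net, "planted_network"))
  if (n < 2) abort("`n` must be at least 2.")
  if (levels != 0 && levels < 2) abort("`levels` must be 0 or >= 2.")
  R <- implied_correlation(net)
  L <- chol(R)
  z <- withr::with_seed(seed, matrix(rnorm(n * ncol(R)), n) %*% L)
  colnames(z) <- net$nodes
  finish_cohort(z, levels, occasion, thresholds)
}

finish_cohort <- function(z, levels, occasion, thresholds = NULL) {
  scores <- discretize_latent(z, levels, thresholds)
  out <- as_cohort(scores, occasion = occasion, levels = levels)
  attr(out, "latent") <- z
  out
}

discretize_latent <- function(z, levels, thresholds = NULL) {
  if (levels == 0) return(z)
  cuts <- thresholds %||% qnorm(seq_len(levels - 1) / levels)
  if (length(cuts) != levels - 1 || is.unsorted(cuts, strictly = TRUE)) {
    abort("`thresholds` must be `levels - 1` strictly increasing cut points.")
  }
  s <- matrix(
    findInterval(z, cuts) + 1L, nrow(z), ncol(z),
    dimnames = dimnames(z)
  )
  storage.mode(s) <- "double"
  s
}

#' Sample paired pre/post cohorts with within-subject dependence
#'
#' Latent draws for the two occasions share a subject-level standard normal
#' component `u`: occasion-specific latents are
#' `L' (sqrt(rho) u + sqrt(1 - rho) e)`, where `L` is the Cholesky factor of
#' that occasion's implied correlation matrix and `e` is occasion-specific
#' noise. Each occasion's marginal correlation structure therefore matches
#' its own network exactly, and when the two networks coincide the per-node
#' latent pre/post correlation equals `subject_rho` exactly (slightly below
#' it otherwise).
#'
#' @param pre_net,post_net planted networks sharing node labels.
#' @param n number of subjects.
#' @param subject_rho within-subject latent correlation in \[0, 1).
#' @param levels,thresholds see [sample_cohort()].
#' @param seed integer seed.
#' @return A list with elements `pre` and `post`, cohorts with aligned
#'   `subject_id`s.
#' @export
make_pre_post <- function(pre_net, post_net, n, subject_rho = 0.5,
                          levels = 5, thresholds = NULL, seed = 1) {
  stopifnot(inherits(pre_net, "planted_network"),
            inherits(post_net, "planted_network"))
  if (!identical(pre_net$nodes, post_net$nodes)) {
    abort("`pre_net` and `post_net` must share identical node labels.")
  }
  if (subject_rho < 0 || subject_rho >= 1) {
    abort("`subject_rho` must lie in [0, 1).")
  }
  k <- length(pre_net$nodes)
  draws <- withr::with_seed(seed, list(
    u = matrix(rnorm(n * k), n),
    e_pre = matrix(rnorm(n * k), n),
    e_post = matrix(rnorm(n * k), n)
  ))
  mix <- function(e) sqrt(subject_rho) * draws$u + sqrt(1 - subject_rho) * e
  z_pre <- mix(draws$e_pre) %*% chol(implied_correlation(pre_net))
  z_post <- mix(draws$e_post) %*% chol(implied_correlation(post_net))
  colnames(z_pre) <- colnames(z_post) <- pre_net$nodes
  pre <- finish_cohort(z_pre, levels, "pre", thresholds)
  post <- finish_cohort(z_post, levels, "post", thresholds)
  post$subject_id <- pre$subject_id
  list(pre = pre, post = post)
}
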