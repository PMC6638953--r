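#' Packaged demo scenario: chained pre network, block-reorganized post
#'
#' The pre-intervention truth contains the two dominant chains of a
#' mindfulness questionnaire network — a transversal
#' mindfulness/self-compassion chain (weights 0.33, 0.29, 0.22, 0.23, 0.25,
#' 0.22) and a clinical-symptom/rumination chain (0.45, 0.18, 0.20, 0.21) —
#' embedded in six weakly connected construct communities (within-block
#' partial correlation 0.12, below the 0.15 path-extraction threshold) with
#' two negative distress-mindfulness edges. The post-intervention truth
#' reorganizes the same 25 nodes into five denser blocks (within-block
#' 0.18): a clinical cluster absorbs thought/emotion suppression, and the
#' adaptive constructs regroup.
#'
#' @return A list with `planted_network`s `pre` and `post`.
#' @export
demo_scenario <- function() {
  pre <- make_planted_network(
    nodes = psychonectome_nodes(),
    chains = list(
      list(nodes = c("FFMQ-O", "MAIA", "EQ", "NAS", "SCS-M", "SCS-K", "SCS-H"),
           weights = c(0.33, 0.29, 0.22, 0.23, 0.25, 0.22)),
      list(nodes = c("DASS-A", "DASS-S", "DASS-D", "RRS-B", "RRS-R"),
           weights = c(0.45, 0.18, 0.20, 0.21))
    ),
    blocks = list(
      list(nodes = c("FFMQ-O", "MAIA", "EQ", "NAS", "SCS-M", "SCS-K", "SCS-H"),
           weight = 0.12),
      list(nodes = c("DASS-A", "DASS-S", "DASS-D", "RRS-B", "RRS-R"),
           weight = 0.12),
      list(nodes = c("FFMQ-D", "FFMQ-A", "FFMQ-J", "FFMQ-R", "ACS"),
           weight = 0.12),
      list(nodes = c("SWLS", "LOT", "PHI"), weight = 0.12),
      list(nodes = c("CSP", "IRI-E"), weight = 0.12),
      list(nodes = c("WBSI", "ERQ-R", "ERQ-S"), weight = 0.12)
    ),
    negative_edges = list(
      list(from = "FFMQ-R", to = "DASS-S", weight = -0.12),
      list(from = "SCS-H", to = "DASS-A", weight = -0.12)
    ),
    description = "demo pre: two dominant chains in six construct communities"
  )
  post <- make_planted_network(
    nodes = psychonectome_nodes(),
    blocks = list(
      list(nodes = c("DASS-A", "DASS-S", "DASS-D", "WBSI", "ERQ-S", "RRS-B"),
           weight = 0.18),
      list(nodes = c("FFMQ-O", "FFMQ-D", "FFMQ-A", "FFMQ-J", "FFMQ-R", "MAIA"),
           weight = 0.18),
      list(nodes = c("EQ", "NAS", "ACS", "ERQ-R", "RRS-R"), weight = 0.18),
      list(nodes = c("SCS-K", "SCS-H", "SCS-M", "CSP", "IRI-E"),
           weight = 0.18),
      list(nodes = c("SWLS", "LOT", "PHI"), weight = 0.18)
    ),
    negative_edges = list(
      list(from = "DASS-S", to = "FFMQ-R", weight = -0.12),
      list(from = "WBSI", to = "EQ", weight = -0.10)
    ),
    description = "demo post: five reorganized construct blocks"
  )
  list(pre = pre, post = post)
}

#' Default pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Any subset can be
#' overridden through `...` (or by editing the returned list); unknown keys
#' are rejected at validation time.
#'
#' @param ... named overrides of the defaults, e.g. `n_subjects = 500`,
#'   `estimator = list(folds = 5)` (sub-lists are merged key-wise).
#' @return A named list of class `psy_config`.
#' @export
pipeline_config <- function(...) {
  config <- list(
    scenario = "demo",        # "demo", or list(pre = , post = ) planted nets
    input = NULL,             # or list(pre = "pre.csv", post = "post.csv")
    n_subjects = 182,
    levels = 5,
    subject_rho = 0.5,
    mcar_rate = 0.108,
    impute = TRUE,
    seed = 42,
    # screening = "min" mirrors the liberal CV-minimum adaptive lasso used
    # in published questionnaire networks (density ~40% at n=182); the
    # conservative "1se" screen is the low-level estimator default.
    estimator = list(folds = 10, n_lambda = 50, lambda_min_ratio = 1e-4,
                     rule = "and", screening = "min"),
    topology = list(path_threshold = 0.15, max_paths = 5,
                    clustering_variant = "onnela", layout_iterations = 500),
    spinglass = list(gamma = 1, start_temp = 1, stop_temp = 0.01,
                     cooling_factor = 0.99, spins = 25, restarts = 10),
    robustness = list(edge_boot_B = 100, case_drop_B = 0,
                      proportions = seq(0.1, 0.7, by = 0.2)),
    output_dir = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(config)) abort(sprintf("Unknown config key: %s", nm))
    if (is.list(config[[nm]]) && is.list(dots[[nm]]) &&
        !inherits(dots[[nm]], "planted_network") && nm != "scenario" &&
        nm != "input") {
      bad <- setdiff(names(dots[[nm]]), names(config[[nm]]))
      if (length(bad)) {
        abort(sprintf("Unknown config key: %s$%s", nm, bad[1]))
      }
      config[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      config[[nm]] <- dots[[nm]]
    }
  }
  structure(config, class = c("psy_config", "list"))
}

#' @rdname pipeline_config
#' @param path YAML file with config keys.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

validate_config <- function(config) {
  bad <- character(0)
  chk <- function(cond, key) if (!cond) bad <<- c(bad, key)
  chk(is.numeric(config$n_subjects) && config$n_subjects >= 2, "n_subjects")
  chk(config$levels == 0 || config$levels >= 2, "levels")
  chk(config$subject_rho >= 0 && config$subject_rho < 1, "subject_rho")
  chk(config$mcar_rate >= 0 && config$mcar_rate <= 0.5, "mcar_rate")
  chk(is.numeric(config$seed), "seed")
  chk(config$estimator$folds >= 2 && 3 * config$estimator$folds < config$n_subjects,
      "estimator$folds")
  chk(config$topology$path_threshold > 0, "topology$path_threshold")
  chk(config$spinglass$stop_temp > 0 &&
        config$spinglass$start_temp > config$spinglass$stop_temp,
      "spinglass$start_temp/stop_temp")
  chk(config$spinglass$cooling_factor > 0 &&
        config$spinglass$cooling_factor < 1, "spinglass$cooling_factor")
  chk(config$spinglass$spins >= 2, "spinglass$spins")
  if (length(bad)) {
    abort(sprintf("Invalid config key(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(config)
}

#' Run the full pre/post network pipeline
#'
#' Orchestrates, deterministically from one seed: cohort simulation (or
#' loading), MCAR masking, EM imputation, Spearman matrices, adaptive-LASSO
#' network estimation for both layers, topological characterization
#' (centrality tables, path extraction, layouts), spinglass communities,
#' bootstrap edge accuracy (and optional case-dropping stability), and the
#' pre/post comparison report. All artifacts are written as plain-text
#' files under `output_dir` together with a JSON manifest (package version,
#' seeds, config hash) and a short human-readable summary.
#'
#' @param config a [pipeline_config()] (or list coercible to one).
#' @param output_dir where to write artifacts (overrides
#'   `config$output_dir`; defaults to a temporary directory).
#' @return Invisibly, a list with every intermediate object plus
#'   `output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  if (!inherits(config, "psy_config")) config <- do.call(pipeline_config, config)
  validate_config(config)
  out_dir <- output_dir %||% config$output_dir %||%
    file.path(tempdir(), paste0("psychonectome-run-", config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("truth", "cohorts", "preprocess", "networks", "topology",
              "communities", "robustness", "compare")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  seeds <- substream_seeds(config$seed, 8)

  # --- data ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    pre_raw <- read_cohort(config$input$pre)
    post_raw <- read_cohort(config$input$post)
  } else {
    truth <- if (identical(config$scenario, "demo")) demo_scenario()
             else config$scenario
    stopifnot(inherits(truth$pre, "planted_network"),
              inherits(truth$post, "planted_network"))
    cohorts <- make_pre_post(truth$pre, truth$post, n = config$n_subjects,
                             subject_rho = config$subject_rho,
                             levels = config$levels, seed = seeds[1])
    pre_raw <- cohorts$pre
    post_raw <- cohorts$post
    if (config$mcar_rate > 0) {
      pre_raw <- apply_mcar(pre_raw, config$mcar_rate, seed = seeds[2])
      post_raw <- apply_mcar(post_raw, config$mcar_rate, seed = seeds[3])
    }
    write_planted_network(truth$pre, file.path(out_dir, "truth", "pre.tsv"))
    write_planted_network(truth$post, file.path(out_dir, "truth", "post.tsv"))
    write_cohort(pre_raw, file.path(out_dir, "cohorts", "pre.csv"),
                 extra = list(seed = seeds[1], truth = "truth/pre.tsv"))
    write_cohort(post_raw, file.path(out_dir, "cohorts", "post.csv"),
                 extra = list(seed = seeds[1], truth = "truth/post.tsv"))
  }

  # --- preprocessing ------------------------------------------------------
  pre_c <- if (config$impute) em_impute(pre_raw) else pre_raw
  post_c <- if (config$impute) em_impute(post_raw) else post_raw
  write_cohort(pre_c, file.path(out_dir, "preprocess", "pre_imputed.csv"))
  write_cohort(post_c, file.path(out_dir, "preprocess", "post_imputed.csv"))
  sp_pre <- spearman_matrix(pre_c)
  sp_post <- spearman_matrix(post_c)
  write_correlation(sp_pre, file.path(out_dir, "preprocess", "spearman_pre.csv"))
  write_correlation(sp_post, file.path(out_dir, "preprocess", "spearman_post.csv"))

  # --- estimation ---------------------------------------------------------
  est <- config$estimator
  net_pre <- estimate_network(pre_c, folds = est$folds, seed = seeds[4],
                              rule = est$rule, screening = est$screening,
                              n_lambda = est$n_lambda,
                              lambda_min_ratio = est$lambda_min_ratio,
                              layer = "pre")
  net_post <- estimate_network(post_c, folds = est$folds, seed = seeds[4],
                               rule = est$rule, screening = est$screening,
                               n_lambda = est$n_lambda,
                               lambda_min_ratio = est$lambda_min_ratio,
                               layer = "post")
  for (fmt in c("tsv", "csv", "graphml")) {
    ext <- c(tsv = "tsv", csv = "csv", graphml = "graphml")[fmt]
    write_network(net_pre, file.path(out_dir, "networks", paste0("pre.", ext)),
                  format = fmt)
    write_network(net_post, file.path(out_dir, "networks", paste0("post.", ext)),
                  format = fmt)
  }

  # --- topology -----------------------------------------------------------
  topo <- config$topology
  tab_pre <- centrality_table(net_pre, topo$clustering_variant)
  tab_post <- centrality_table(net_post, topo$clustering_variant)
  readr::write_csv(as_tibble(tab_pre),
                   file.path(out_dir, "topology", "centrality_pre.csv"))
  readr::write_csv(as_tibble(tab_post),
                   file.path(out_dir, "topology", "centrality_post.csv"))
  readr::write_csv(centrality_z(tab_pre),
                   file.path(out_dir, "topology", "centrality_z_pre.csv"))
  readr::write_csv(centrality_z(tab_post),
                   file.path(out_dir, "topology", "centrality_z_post.csv"))
  paths_pre <- find_paths(net_pre, topo$path_threshold, topo$max_paths)
  paths_post <- find_paths(net_post, topo$path_threshold, topo$max_paths)
  jsonlite::write_json(paths_pre, file.path(out_dir, "topology", "paths_pre.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(paths_post, file.path(out_dir, "topology", "paths_post.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(fr_layout(net_pre, topo$layout_iterations, seed = seeds[5]),
                   file.path(out_dir, "topology", "layout_pre.csv"))
  readr::write_csv(fr_layout(net_post, topo$layout_iterations, seed = seeds[5]),
                   file.path(out_dir, "topology", "layout_post.csv"))

  # --- communities --------------------------------------------------------
  sg <- config$spinglass
  part_pre <- spinglass(net_pre, gamma = sg$gamma, start_temp = sg$start_temp,
                        stop_temp = sg$stop_temp,
                        cooling_factor = sg$cooling_factor, spins = sg$spins,
                        restarts = sg$restarts, seed = seeds[6])
  part_post <- spinglass(net_post, gamma = sg$gamma, start_temp = sg$start_temp,
                         stop_temp = sg$stop_temp,
                         cooling_factor = sg$cooling_factor, spins = sg$spins,
                         restarts = sg$restarts, seed = seeds[6])
  write_partition(part_pre, file.path(out_dir, "communities", "pre.csv"))
  write_partition(part_post, file.path(out_dir, "communities", "post.csv"))

  # --- robustness ---------------------------------------------------------
  rb <- config$robustness
  edge_ci_pre <- edge_ci_post <- stability <- NULL
  if (rb$edge_boot_B >= 100) {
    edge_ci_pre <- bootstrap_edges(pre_c, B = rb$edge_boot_B, seed = seeds[7],
                                   folds = est$folds,
                                   screening = est$screening)
    edge_ci_post <- bootstrap_edges(post_c, B = rb$edge_boot_B, seed = seeds[7],
                                    folds = est$folds,
                                    screening = est$screening)
    write_edge_ci(edge_ci_pre, file.path(out_dir, "robustness", "edge_ci_pre.tsv"))
    write_edge_ci(edge_ci_post, file.path(out_dir, "robustness", "edge_ci_post.tsv"))
  }
  if (rb$case_drop_B > 0) {
    stability <- case_drop_stability(pre_c, proportions = rb$proportions,
                                     B = rb$case_drop_B, seed = seeds[8],
                                     folds = est$folds)
    write_stability(stability, file.path(out_dir, "robustness", "case_drop_pre.csv"))
  }
  pred_pre <- predictability(pre_c)
  pred_post <- predictability(post_c)
  readr::write_csv(as_tibble(pred_pre),
                   file.path(out_dir, "robustness", "predictability_pre.csv"))
  readr::write_csv(as_tibble(pred_post),
                   file.path(out_dir, "robustness", "predictability_post.csv"))

  # --- compare ------------------------------------------------------------
  report <- compare_pre_post(pre_c, post_c, net_pre, net_post,
                             part_pre, part_post)
  readr::write_csv(report$tests, file.path(out_dir, "compare", "paired_tests.csv"))
  readr::write_csv(report$deltas, file.path(out_dir, "compare", "centrality_deltas.csv"))
  readr::write_csv(report$top_movers, file.path(out_dir, "compare", "top_movers.csv"))
  readr::write_csv(report$layer_correlations,
                   file.path(out_dir, "compare", "layer_correlations.csv"))

  # --- manifest -----------------------------------------------------------
  config_json <- unclass(config)
  if (!is.character(config_json$scenario)) {
    config_json$scenario <- "custom planted networks (see truth/)"
  }
  manifest <- list(
    package = "psychonectome",
    version = as.character(utils::packageVersion("psychonectome")),
    config = config_json,
    config_hash = rlang::hash(unclass(config)),
    stage_seeds = seeds,
    densities = list(pre = network_density(net_pre),
                     post = network_density(net_post)),
    communities = list(pre = attr(part_pre, "n_communities"),
                       post = attr(part_post, "n_communities"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("psychonectome pipeline run (seed %s)", config$seed),
    sprintf("pre : %d/%d edges (%.2f%%), %d communities",
            network_density(net_pre)$edges, network_density(net_pre)$potential,
            network_density(net_pre)$percent, attr(part_pre, "n_communities")),
    sprintf("post: %d/%d edges (%.2f%%), %d communities",
            network_density(net_post)$edges, network_density(net_post)$potential,
            network_density(net_post)$percent, attr(part_post, "n_communities")),
    sprintf("mean predictability pre %.3f / post %.3f",
            attr(pred_pre, "mean_r_squared"), attr(pred_post, "mean_r_squared")),
    sprintf("edge-weight cross-layer correlation %.3f",
            report$layer_correlations$correlation[
              report$layer_correlations$quantity == "edge_weights"])
  ), file.path(out_dir, "summary.txt"))

  invisible(list(
    output_dir = out_dir, config = config, truth = truth,
    pre_raw = pre_raw, post_raw = post_raw,
    pre_cohort = pre_c, post_cohort = post_c,
    spearman = list(pre = sp_pre, post = sp_post),
    networks = list(pre = net_pre, post = net_post),
    centrality = list(pre = tab_pre, post = tab_post),
    paths = list(pre = paths_pre, post = paths_post),
    partitions = list(pre = part_pre, post = part_post),
    edge_ci = list(pre = edge_ci_pre, post = edge_ci_post),
    stability = stability,
    predictability = list(pre = pred_pre, post = pred_post),
    report = report
  ))
}

#' Fig-3-style z-scored centrality data
#'
#' Long-format centrality values standardized within each index, the usual
#' input for centrality profile plots.
#'
#' @param table a [centrality_table()].
#' @return A tibble with columns `node`, `index`, `value`, `z`.
#' @export
centrality_z <- function(table) {
  as_tibble(table) |>
    tidyr::pivot_longer(-"node", names_to = "index", values_to = "value") |>
    group_by(.data$index) |>
    mutate(z = if (sd(.data$value) > 0) {
      (.data$value - mean(.data$value)) / sd(.data$value)
    } else {
      .data$value * 0
    }) |>
    ungroup()
}
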