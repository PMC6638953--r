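Package: psychonectome
Title: Regularized Partial-Correlation Network Analysis of Pre/Post
    Questionnaire Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and compares psychometric networks ("psychonectomes")
    from ordinal questionnaire data collected before and after an
    intervention. Provides a Gaussian-copula synthetic-cohort generator with
    planted partial-correlation structure, expectation-maximization
    imputation for missing-at-random entries, Spearman and polychoric
    correlation matrices, nodewise adaptive-LASSO estimation of regularized
    partial-correlation networks, signed network topology (expected
    influence, strength, degree, weighted clustering, efficiency, path
    extraction, force-directed layouts), signed spinglass community
    detection, predictability, bootstrap edge accuracy and case-dropping
    centrality stability, and paired pre/post comparison, with tidy
    accessors and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    mvtnorm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
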