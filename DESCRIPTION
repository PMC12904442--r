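Package: pancox
Title: Pan-Cancer and Single-Cancer Prognostic Modeling with
    Left-Truncated Lasso Cox Regression
Version: 0.1.0
Authors@R:
    person("pancox", "maintainers", email = "maintainers@pancox.dev",
           role = c("aut", "cre"))
Description: A reproducible pipeline for building and benchmarking
    prognostic overall-survival models on clinico-genomic cohorts.
    Provides a synthetic cohort generator with delayed database entry
    (left truncation), prognostic laboratory trajectories and panel
    genomics; windowed lab time-series feature engineering; k-nearest
    neighbour and chained-equation imputation; a lasso-penalized Cox
    proportional-hazards solver with risk-set adjustment for left
    truncation, cross-validated penalty selection by concordance, and
    Breslow baseline hazards; evaluation by concordance index,
    integrated Brier score and median-split risk stratification with
    bias-corrected bootstrap intervals; and an experiment harness that
    contrasts pan-cancer with single-cancer training scopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
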