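Package: prwalk
Title: Persistent Random Walk Analysis of 3D Cell Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing 3D single-cell migration tracks under a
    heterogeneous persistent random walk model. Provides a trajectory
    simulator with per-step ground truth, classical motility metrics
    (mean track speed, arrest coefficient, mean squared displacement,
    turning angles) with eligibility filters, grid-based sequential
    Bayesian inference of time-varying persistence and activity from
    velocity series, and a semi-unsupervised sub-population pipeline
    (DBSCAN outlier removal, k-means clustering of per-cell parameter
    averages, labelled cluster merging, bootstrap proportion stability,
    two-proportion z tests, and highest-density-region contour
    summaries). All user-facing functions take and return tidy data
    frames so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
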