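Package: starmaze
Title: Star-Maze Navigation Metrics, Strategy Classification and Learning Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for star-maze spatial-navigation experiments in
    which a participant walks a five-alley maze radiating from a regular
    pentagon to find a hidden reward. Provides a parametric maze model and the
    canonical two-task trial protocol; strict readers and writers for sampled
    planar trajectories and cohort manifests; per-trial navigation metrics
    (success, visited alleys, total path length, duration, mean speed,
    distance error and rotation angle); egocentric versus allocentric strategy
    classification of test and compelled trials; detection of the learning-curve
    stabilization trial ("knee") by a Friedman/Wilcoxon criterion; the study's
    nonparametric group statistics, Spearman correlations with visuospatial
    test z-scores and post-hoc power; and a seeded agent-based simulator that
    generates complete synthetic cohorts with controllable strategy, learning
    dynamics and noise for end-to-end testing and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    nortest,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
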