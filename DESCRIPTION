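Package: fmrievents
Title: Data-Informed Event Models for GLM Analysis of Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction, evaluation and data-driven optimisation of event
    models for general linear model (GLM) analysis of task-based fMRI BOLD
    time series. Builds event regressors by convolving boxcar neural time
    series with a sampled haemodynamic response function (single-gamma or
    double-gamma), fits per-region-of-interest linear models and reports
    R-squared and BIC fit summaries, and searches for event onsets and
    durations that maximise weighted model fit under user constraints with
    an elitist genetic algorithm. Includes a synthetic BOLD generator and
    interval-overlap metrics for validating recovered event timing, plus
    readers and writers for the long-table file formats involved.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
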