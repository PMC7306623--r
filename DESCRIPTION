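Package: errmon
Title: Performance Monitoring and Error Detection Analysis for Go/Nogo EEG
    Experiments
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for performance-monitoring
    Go/Nogo EEG experiments in clinical cohorts. Provides a calibrated
    synthetic-cohort generator (behavioral sessions plus forward-modelled
    multichannel EEG), BrainVision Core format input/output, preprocessing
    with EOG regression, epoching, amplitude-based artifact rejection and
    spherical-spline current source density (surface Laplacian) transforms,
    quantification of stimulus-locked (N2, P3) and response-locked
    (Ne/ERN, CRN, Pe, Pc) event-related potential components, sliding-window
    multivariate decoding of correct versus error responses with a
    shuffled-label empirical null, and the group-level statistics layer:
    pooled and paired t-tests, JZS Bayes factors, 2x2 mixed ANOVA with
    Greenhouse-Geisser machinery, correlations and simple regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
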