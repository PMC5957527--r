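Package: avoidgen
Title: Generative Modelling of Instrumental Avoidance Generalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling how instrumental avoidance generalizes
    across perceptually similar stimuli. Implements hybrid
    Rescorla-Wagner/Pearce-Hall Q-learning agents with perceptual
    confusion and Gaussian value-based generalization (separate widths
    for aversive and neutral feedback), hierarchical empirical-Bayes
    model fitting with Laplace model evidence, random-effects Bayesian
    model selection with exceedance probabilities, lapse-bounded
    psychometric function fitting and 75% discrimination thresholds,
    behavioural summaries (relative generalization-stimulus avoidance,
    peak-shift asymmetry, quality-control filters, Nyholt-Bonferroni
    effective-number correction, precision-weighted regression),
    cross-validated linear discriminant contrast (crossnobis) distances
    for multivariate pattern data, and synthetic-cohort generators that
    emulate the behavioural task for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
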