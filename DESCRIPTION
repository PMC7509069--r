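Package: ssomcda
Title: Longitudinal Cognitive Diagnosis with Supervised Self-Organizing Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal cognitive diagnostic assessment built
    around a hidden Markov model whose measurement model is a supervised
    self-organizing map (SSOM). Provides a DINA-model simulator for
    dichotomous item responses over repeated time points with correlated
    initial attribute profiles and per-attribute Markov transitions; a
    three-layer supervised Kohonen network that classifies examinees into
    attribute-mastery patterns; maximum-likelihood estimation of initial
    state and transition probabilities at attribute and pattern
    granularity; attribute- and pattern-level classification accuracy
    criteria (ACCR, PCCR); and replication runners for simulation studies
    and two-wave empirical workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
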