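Package: semloop
Title: Non-Recursive Structural Equation Modeling for Psychiatric Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for specifying, identifying, and estimating structural
    equation models with feedback loops between latent outcomes, built around
    a cross-sectional student mental-health survey design: deterministic
    scoring of five screening instruments (ASRS-v1.1, PHQ-9, ISI, OSSS-3,
    PIUQ-9) with Wilson prevalence intervals, order- and rank-condition
    identification of simultaneous equations, free-parameter counting and
    N:q sample-size planning, pre-modeling diagnostics (KMO, Bartlett,
    Mardia, Mahalanobis outliers, common-method bias, composite reliability,
    item parceling), a seeded ordinal-item simulator standing in for an
    undeposited survey, maximum-likelihood estimation in RAM form with
    bootstrap inference and stability analysis, fit indices with
    modification indices, and direct/indirect effect decomposition through
    the depression pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    numDeriv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr
Config/testthat/edition: 3
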