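Package: msprogbench
Title: Predicting Confirmed Disability Progression in Multiple Sclerosis from
    Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for predicting 2-year
    confirmed disability progression in multiple sclerosis from routinely
    collected registry data. Provides a seeded synthetic registry generator
    with a known ground-truth risk law, clinical-episode extraction with the
    six-month confirmation and relapse-exclusion rules on the Expanded
    Disability Status Scale (EDSS), static/dynamic/longitudinal feature
    engineering including disease-modifying-therapy efficacy classes,
    probabilistic neural classifiers (multi-layer perceptron, Monte-Carlo
    dropout Bayesian network, continuous-time temporal attention),
    and center-held-out external validation with discrimination metrics,
    probability calibration (Platt scaling, isotonic regression, expected
    calibration error), reliability diagrams and permutation feature
    importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
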