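Package: agetree
Title: Healthy-Ageing Indices and Multivariate Regression Trees for Ageing Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite healthy-ageing indices (physical, functional,
    mental, cognition, social) from coded ageing-survey items via polarity
    recoding, min-max scaling and zero-mean centering, and fits from-scratch
    multivariate regression trees that partition respondents on ordinal
    predictors by minimising mean squared error summed over the five indices.
    Includes an eligibility-filter cascade with a stage-by-stage exclusion
    ledger, k-fold cross-validated tree-depth selection, age-stratified fits,
    Graphviz/DOT and text tree rendering, descriptive age-group summaries,
    and a seeded synthetic survey-data generator with planted effects so the
    whole pipeline is testable without access to restricted microdata.
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
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
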