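Package: sadmix
Title: Multiple-Trait Structured Antedependence Mixed Models for
    Longitudinal Genetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multiple-trait structured antedependence (SAD) mixed models
    to longitudinal quantitative-genetic data such as litter size and average
    birth weight recorded over successive parities.  Random genetic and
    pseudo-permanent animal effects follow antedependence recursions whose
    coefficients and log innovation variances are polynomial functions of
    time, with optional cross-antedependence between traits; the model carries
    no separate residual term.  Provides pedigree numerator relationship
    matrices, REML estimation with BLUP breeding-value prediction, a Legendre
    random-regression baseline, likelihood-ratio/AIC stepwise model selection,
    a synthetic-data generator emulating pig- and rabbit-style reproduction
    designs, and heritability/correlation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
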