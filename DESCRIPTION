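Package: pafbias
Title: Population Attributable Fractions from Summary Data and the Bias
    of Levin's Formula Under Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes population attributable fractions (PAF) from summary
    statistics (exposure prevalence, unadjusted and causal relative risks)
    and from fully specified confounder-stratified populations. Implements
    Levin's formula, Miettinen's case-prevalence formula and its
    three-variable re-expression, quantifies the asymptotic bias of Levin's
    formula as a function of the confounding ratio, handles effect
    modification of the causal relative risk across confounder strata, and
    generalises every estimator to multi-category and continuous exposures
    via summation and trapezoid quadrature. Ships seeded synthetic-population
    generators so every estimator can be checked against the counterfactual
    definition of the PAF without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
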