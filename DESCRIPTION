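Package: itsurv
Title: Interrupted Time-Series Counterfactual Analysis of Surveillance Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interrupted time-series (ITS) analysis of monthly
    event-surveillance counts, built around emergency-department visit
    monitoring. Fits negative binomial count models with a linear trend,
    optional Fourier (harmonic) seasonality and a population offset to a
    pre-intervention window, selects the harmonic degree by AIC,
    extrapolates the fitted model through the intervention window as a
    counterfactual, and summarises each intervention year as observed and
    adjusted incidence ratios with parametric-bootstrap confidence
    intervals and p-values. Also provides a before/during characteristics
    table (Fisher exact and Mann-Whitney U tests), a synthetic-data
    generator with known ground truth for validation, plotting of observed
    versus expected series, and a config-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    MASS,
    stats,
    utils,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
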