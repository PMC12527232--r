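Package: claimsbias
Title: Quantifying External-Validity Bias in Healthcare Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how far inpatient procedure rates estimated
    from a nonrandomly sampled commercial insurance ("claims") cohort deviate
    from ground-truth population rates, and to relate that bias to
    neighborhood-level social determinants of health (SDOH). Provides
    person-year exposure accounting, exact (Garwood) Poisson rate confidence
    intervals, delta-method intervals for claims/reference rate ratios,
    zip-level Poisson regression of procedure counts on an SDOH metric with a
    population offset, a second-stage log-linear meta-regression of the bias
    on those slopes, population-weighted tract-to-zip SDOH aggregation and a
    PCA-based socioeconomic index, and a seeded synthetic-data generator that
    emulates SDOH-dependent selection into commercial insurance together with
    exact analytic oracles for the expected bias.
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
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
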