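Package: countymort
Title: Small-Area Estimation of County Mortality Rates and Racial-Ethnic
    Disparities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating cause-specific mortality rates by county,
    racial-ethnic group, sex, age group, and year from stratified death and
    population counts. Implements cause mapping and proportional
    redistribution of garbage-coded deaths, a hierarchical Poisson
    small-area model with ICAR spatial and first-order random-walk age and
    time effects fit by MAP with a Laplace approximation, simulation of
    posterior rate draws, adjustment for race-ethnicity misclassification
    on death certificates, two-stage iterative-proportional-fitting
    calibration of race- and cause-specific estimates to county totals,
    and summarisation of age-standardised rates, uncertainty intervals,
    absolute and relative disparities, and county disparity censuses.
    Includes a synthetic-data generator with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
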