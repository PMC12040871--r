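Package: hwequity
Title: Equity Analysis of Health Workforce Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the geographic equity of a health
    workforce from unit-level panel data (administrative units by year,
    with population, GDP, land area and worker counts). Implements
    per-capita density series with small-sample linear trend tests,
    dimension-specific Lorenz curves and Gini coefficients (population,
    economy, geography), and Theil T and Theil L entropy indices with
    additive within-region/between-region decomposition. Includes a
    synthetic panel generator with known log-normal inequality structure
    so every estimator can be checked against closed-form references.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
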