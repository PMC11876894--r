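Package: rxtraj
Title: Opioid Dose Trajectory Modeling from Pharmacy Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds new-user opioid cohorts from longitudinal pharmacy-claims
    tables, converts prescription fills to morphine milligram equivalents
    (MME), aggregates mean daily MME over consecutive 30-day windows, fits
    censored-normal group-based trajectory models (GBTM) by an
    expectation-maximisation algorithm with optional time-varying stimulant
    covariates, selects the number of trajectory groups by the Bayesian
    information criterion, and quantifies stimulant-opioid associations via
    trajectory-membership logistic regression and rank-based group
    comparisons. A synthetic-claims generator with known latent-group
    structure makes every stage testable without access to proprietary
    claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
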