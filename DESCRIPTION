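Package: moltstage
Title: Molt-Cycle Milestone Estimation and Staging for Locust Nymphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Locates molt-cycle milestones in fifth-instar locust nymphs from
    daily longitudinal measurements. Fits a Lorentzian model to hemolymph
    ecdysteroid titers, a lognormal trajectory to body-weight gain, and a
    logistic-linked linear-to-constant model to the inter-wing distance by
    weighted nonlinear least squares with reduced chi-square reporting;
    extracts the ecdysteroid peak, weight peak and inter-wing sigmoid
    midpoint as developmental time points with delta-method uncertainties;
    correlates milestones by subtraction of fitted peak locations with
    quadrature error propagation; classifies individual nymphs into molt
    stages (N5IW, N5WP, N5WD) by non-invasive threshold rules; and simulates
    seeded synthetic cohorts so the whole pipeline is testable without
    deposited raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
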