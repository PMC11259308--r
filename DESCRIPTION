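Package: troposim
Title: Discrete-Event Microsimulation of Troponin-Stratified Cardiovascular
    Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-level discrete-event simulation comparing standard
    SCORE-based cardiovascular risk screening against a strategy that
    further stratifies SCORE risk classes by sex-specific high-sensitivity
    troponin I thresholds. Provides a synthetic cohort generator, risk
    stratification and treatment-policy assignment, competing-risk Weibull
    event sampling with common random numbers, discounted QALY and direct
    medical cost accounting, population-level cost-effectiveness measures
    (ICER, INMB, NNS, RRR, event-free survival, potential years of working
    life lost), probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and univariate (tornado) sensitivity analysis,
    all driven by a single validated configuration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
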