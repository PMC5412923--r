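Package: crmineff
Title: Bayesian Adaptive Dose-Finding Designs for an Inefficacy Endpoint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for phase-I dose-finding trials that steer on a
    binary inefficacy endpoint rather than toxicity. Implements a continual
    reassessment method (CRM) on a one-parameter logistic dose-inefficacy
    curve with deterministic grid-quadrature posterior updating, a three-period
    hybrid adaptive design (rule-based escalation, CRM-guided allocation, and
    an optional confirmation cohort), a fixed "5+5+5+5" benchmark design, both
    rule-based and model-based final-dose selection criteria, a bank of true
    dose-inefficacy test scenarios, and an evaluation layer computing
    operating characteristics, summary measures and weighted summary measures
    for design comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
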