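Package: prsmicrosim
Title: Individual-Level Microsimulation of Polygenic Risk Score Guided
    Type 2 Diabetes Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-level four-state (healthy, type 2 diabetes, type 2
    diabetes with complications, death) annual-cycle state-transition model
    for the health-economic evaluation of targeted polygenic risk score (PRS)
    screening added to FINDRISC-based risk assessment. Provides Weibull
    accelerated-failure-time survival machinery with model selection and
    extrapolation, a synthetic FINRISK-like cohort generator, cost and
    quality-adjusted life-year accounting with discounting, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves and
    expected value of perfect information, and a scenario runner for
    discounting, time-horizon and costing-perspective analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
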