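Package: dualkidney
Title: Dual Versus Single Kidney Transplant Outcome Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing dual and single deceased-donor
    kidney transplantation from a resource-utilization perspective: synthetic
    transplant-registry generation calibrated to national registry summaries,
    cohort filtering and single imputation, logit propensity-score estimation
    with greedy k:1 nearest-neighbor matching and standardized-mean-difference
    balance diagnostics, Kaplan-Meier / log-rank / Cox proportional-hazards
    models for patient, all-cause graft and death-censored graft survival, a
    counterfactual projection of additional successful transplants if dual
    kidneys were transplanted singly, and a discrete-time three-state
    microsimulation of waitlist mortality under alternative allocation
    pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
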