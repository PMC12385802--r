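Package: psascreen
Title: Risk-Stratified Prostate Cancer Screening Pathway Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for organized, risk-adapted
    prostate cancer screening programmes of the kind piloted in Lombardy:
    a synthetic-cohort generator calibrated to a log-normal PSA distribution,
    the questionnaire eligibility and PSA/family-history triage rules, the
    specialist pathway state machine (urology outcome, PI-RADS x PSA-density
    biopsy decision table), programme performance metrics (uptake,
    eligibility, referral rate, risk stratification), a closed-form
    cancer-yield projection model over participation scenarios, and two-arm
    proportion comparisons with Wald confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
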