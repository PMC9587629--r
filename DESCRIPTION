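Package: troponinCEA
Title: Cost-Effectiveness of Emergency Primary Care Triage of Low-Risk
    Chest Pain with the ESC 0/1-h Troponin Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing assessment
    of low-risk chest-pain patients with the ESC 0/1-h high-sensitivity
    cardiac troponin T algorithm in emergency primary care against routine
    hospital admission, from the Norwegian health-system perspective.
    Provides a deterministic decision-tree cost model with micro-costing
    conversion rules, a waiting-time and excess-event QALY model, a
    three-state (non-CVD, CVD, dead) Markov cohort model with half-cycle
    correction and discounting, base-case and conservative scenario
    analysis, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, national budget-impact projection by laboratory
    catchment coverage, a diagnostic-accuracy worked example, and a seeded
    synthetic patient-cohort generator standing in for the study-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
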