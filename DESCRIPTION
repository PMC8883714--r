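Package: cwpcea
Title: Cost-Effectiveness Analysis of Coal Workers' Pneumoconiosis Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Time-dependent three-state Markov cohort model (health,
    coal workers' pneumoconiosis, death) for evaluating dust-control
    interventions in coal mines from the enterprise perspective.
    Implements generalised cost-effectiveness analysis (GCEA)
    counterfactual construction by back-adjusting incidence for
    intervention coverage and efficiency, life-table incidence
    estimation, discounted half-cycle-corrected QALY accrual,
    incremental cost-effectiveness ratios with dominance and frontier
    analysis, GDP-multiple threshold classification, one-way (tornado)
    sensitivity analysis, and probabilistic sensitivity analysis with
    gamma-distributed costs and beta-distributed utilities, including
    cost-effectiveness acceptability curves. A synthetic-data module
    generates realistic transition-probability schedules and life-table
    cohorts so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
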