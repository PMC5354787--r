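Package: nsclcCEA
Title: Cost-Effectiveness Modelling of First-Line EGFR-Targeted Therapy in Advanced NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision-analytic cost-effectiveness model comparing four first-line
    strategies for EGFR-mutation-positive advanced non-small cell lung cancer in
    the Chinese setting: pemetrexed-cisplatin chemotherapy (PC), PC followed by
    pemetrexed maintenance, gefitinib, and icotinib.  Provides a typed registry of
    clinical, cost and utility parameters with probabilistic-sensitivity-analysis
    distributions; Weibull progression-free-survival modelling with hazard-ratio
    scale adjustment and a log-log least-squares Kaplan-Meier fitter; a
    frequentist random-effects network meta-analysis of trial hazard ratios; a
    21-day-cycle, 10-year Markov cohort engine with discounted cost and QALY
    accrual, serious-adverse-event terms, salvage and terminal care, EGFR-test
    amortization and patient-assistance-program drug-cost caps; incremental
    cost-effectiveness analysis with dominance classification; and one-way
    (tornado) plus probabilistic sensitivity analyses with cost-effectiveness
    acceptability curves.  Synthetic-data generators emulate Kaplan-Meier curves
    and multi-trial hazard-ratio networks so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
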