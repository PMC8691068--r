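Package: nassim
Title: Monte Carlo Probability-Tree Simulation of Neonatal Abstinence
    Syndrome System Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cohort microsimulation of Medicaid-enrolled women with opioid
    use disorder through pregnancy, treatment and outcome stages, encoded as
    a probability tree whose topology and transition probabilities are data.
    Four system-level interventions (mandatory opioid testing, patient
    navigators, treatment-capacity expansion, peer recovery coaches) and
    their combinations are composed as transition modifiers, and incremental
    costs are aggregated from a Medicaid payer perspective and a total-system
    perspective that adds overdose-death productivity loss, living-with-OUD
    healthcare costs and special-education costs. Includes an exact
    path-enumeration oracle for the Monte Carlo engine, replicated scenario
    runs with common random numbers, results tables with percent differences
    and significance flags, a claims-style cohort-extraction validation
    pathway, and seeded generators for synthetic parameter sets and
    synthetic claims with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
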