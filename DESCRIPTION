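Package: periRisk
Title: Peri-Implantitis Risk Scores (PRA and IRA) with Survival-Based Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based calculation of two patient-level peri-implantitis
    risk scores used during supportive periodontal and implant maintenance:
    the six-parameter Periodontal Risk Assessment (PRA) and an
    eight-parameter Implant Risk Assessment (IRA) adapted from the IDRA
    score. Implements the peri-implantitis case definition (probing depth
    >= 6 mm with bleeding/suppuration and radiographic bone level >= 3 mm),
    a seeded synthetic-cohort generator with configurable category-dependent
    event hazards, and a validation pipeline: Kaplan-Meier curves, log-rank
    tests, univariable Cox models for high versus low/moderate risk,
    ordinal-score ROC/AUC, confusion-matrix metrics reconstructed from
    published summaries, and Cohen's kappa between scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
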