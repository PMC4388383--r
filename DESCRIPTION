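Package: glp1ce
Title: Short-Term Decision-Tree Cost-Effectiveness Modelling of GLP-1
    Receptor Agonist Strategies in Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Evaluates the short-term (6- and 12-month) cost-effectiveness
    of once-daily liraglutide 1.8 mg versus once-weekly exenatide 2 mg in
    type 2 diabetes mellitus with a two-strategy decision tree. Effectiveness
    is measured as reduction in glycated hemoglobin (HbA1c); the model
    tracks treatment discontinuation before and after week 4,
    gastrointestinal adverse-event costs, and drug acquisition cost, and
    reports the incremental cost per 1% HbA1c reduction. Includes one-way
    sensitivity analysis with tornado ranking, a seeded probabilistic
    sensitivity analysis with beta/normal distributions fitted from interval
    summaries, cost-effectiveness acceptability curves, a patient-level
    micro-simulation oracle for validating the closed-form cohort
    expectations, and readers/writers for a plain-text scenario format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
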