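Package: lmtscore
Title: Scoring Engine for the FAO Laboratory Mapping Tool Safety Module
Version: 0.1.0
Authors@R:
    person("lmtscore", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Schema-driven implementation of the safety and biosecurity
    module of the FAO Laboratory Mapping Tool (LMT-S), a standardized
    laboratory assessment instrument. Provides the built-in 4-area,
    20-category, 98-subcategory taxonomy with four-level scoring rubrics;
    percentage-of-optimum scoring with Not-applicable and blank handling;
    completion-based confidence bands; radar-band rankings; multi-assessment
    comparison with per-scope deltas; gap analysis against rubric
    progressions; multi-laboratory cohort aggregation (mean, SD, range,
    discrepancy ranking); plain-text workbook, JSON and CSV interchange;
    radar-chart and table rendering; a seeded synthetic-assessment
    generator; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
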