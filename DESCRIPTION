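Package: lowldl
Title: Very Low LDL Cholesterol and Type 2 Diabetes Risk from Electronic
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase electronic-health-record (EHR) analysis pipeline
    relating very low LDL cholesterol, occurring in the absence of statin
    therapy, to type 2 diabetes mellitus. Provides a seeded synthetic EHR
    generator with a known exposure odds ratio for parameter-recovery
    testing; Friedewald LDL-C computation with per-measurement eligibility
    filtering (inpatient, age under 5, low-albumin window, post-statin,
    high triglycerides); median-based low/normal cohort assignment with a
    discovery/validation split; phecode-based case/control/exclusion
    phenotyping and an algorithmic type 2 diabetes classifier; and
    odds-ratio estimation via 2x2 tables and adjusted logistic regression,
    including prespecified stratified, interaction, and sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
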