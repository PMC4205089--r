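Package: ctgaudit
Title: Data-Quality Audits for ClinicalTrials.gov Registry Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits clinical-trial registry records in the classic
    ClinicalTrials.gov XML dialect for machine-readability and currency:
    detection of open-status/past-completion conflicts, classification and
    segmentation of eligibility-criteria textblocks (suggested and extended
    macro-formats), rule-based annotation of four barrier categories that
    impede automated eligibility screening (sub-populations, laboratory
    values and medical scores, temporal constraints, patient behavior and
    abilities), last-update-stratified follow-up sampling with
    distance-ordered contact plans, and recency comparisons via one-sided
    Mann-Whitney rank-sum tests. Ships a synthetic corpus generator with
    planted ground truth so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
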