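Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FDA Adverse Event
    Reporting System (FAERS) quarterly extracts: parsing and writing the
    dollar-delimited ASCII tables (DEMO, DRUG, REAC, OUTC, INDI, THER),
    FDA-style case deduplication by CASEID/FDA_DT/PRIMARYID, primary-suspect
    cohort construction with indication-based event exclusion, MedDRA Preferred
    Term to System Organ Class mapping from a user-supplied dictionary, 2x2
    contingency tables at PT and SOC level, and four disproportionality
    algorithms (reporting odds ratio, proportional reporting ratio with
    chi-squared, BCPNN information component, and a closed-form empirical
    Bayes geometric mean) with conventional thresholds and a two-method signal
    rule. Includes a synthetic FAERS-like report generator with analytic ground
    truth for validating every pipeline stage without access to the real
    database, descriptive cohort summaries, and a config-driven end-to-end
    pipeline with run accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
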