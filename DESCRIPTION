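Package: oncocdm
Title: Common Data Model Harmonization and Registry-Ready Phenotyping for
    Oncology EHR Extracts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing hospital electronic health record (EHR)
    extracts into a small common data model (CDM) and deriving registry-ready
    facts from it: new-diagnosis inclusion decisions against cancer-registry
    criteria, named treatment regimens inferred from ATC-coded prescription
    streams by same-week episode grouping and catalog matching, CTCAE
    treatment-toxicity signals from laboratory indicators, indicator drug
    orders, admission diagnoses and imaging-report keywords, and
    cross-validation of laboratory items against a manually registered copy.
    Ships a seeded synthetic EHR cohort generator with complete ground truth
    so every engine can be scored (positive-predictive-value accuracy tables)
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
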