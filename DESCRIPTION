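Package: covalid
Title: Content Validity of Patient-Reported Outcome Measures via ICF Linking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the content validity of patient-reported outcome
    (PRO) measures against the WHO International Classification of Functioning,
    Disability and Health (ICF). Implements the survey-construction ledger that
    maps ICF categories to survey items, dichotomization of 4-point Likert
    responses and threshold-based relevance rules across patient, proxy and
    healthcare-professional rater groups, patient-proxy dyad agreement via
    Cohen's kappa and weighted kappa with large-sample null inference, and
    per-instrument content-coverage scoring of item-to-ICF linking tables under
    three stringency rules. Includes a seeded synthetic-data generator with
    planted relevance sets, dyad agreement structure and coverage expectations,
    plus validated CSV/JSON/YAML readers and writers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
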