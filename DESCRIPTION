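Package: srsignal
Title: Signal Detection and Clinical Prioritization for Spontaneous
    Adverse-Event Reporting Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pharmacovigilance analysis of
    FAERS-style spontaneous-reporting databases: parsing of the quarterly
    '$'-delimited extract tables, two-round case deduplication,
    primary-suspect filtering, MedDRA PT-to-SOC annotation, four
    disproportionality algorithms (reporting odds ratio, proportional
    reporting ratio with chi-square, BCPNN information component, and the
    multi-item gamma-Poisson shrinker with empirical-Bayes geometric mean),
    a semi-quantitative clinical-priority rubric, time-to-onset
    Kaplan-Meier and log-rank analysis, and case/non-case logistic
    modelling of risk factors. A seeded synthetic spontaneous-reporting
    generator with planted drug-event associations makes every stage
    testable without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
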