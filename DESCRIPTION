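Package: mirlit
Title: Rule-Based Mining of microRNA Relations from Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("mirlit", "developers", email = "mirlit@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully offline pipeline for extracting microRNA
    information from biomedical abstracts. Detects miRNA mentions with a
    regular-expression grammar and normalizes them to miRBase-style family
    identifiers; recognizes genes, diseases, biological processes and
    extracellular locations with dictionary matching against OBO ontologies
    and plain-text lexicons; extracts miRNA-gene regulation (including
    direct targeting), miRNA-process connections, miRNA-disease roles
    (biomarker, therapeutic target, outcome, treatment, other),
    differential-expression statements and miRNA-extracellular-location
    pairs using declarative trigger/slot pattern rules over a token-window
    or dependency abstraction; stores annotated documents in a JSON-lines
    corpus with inverted indices supporting miRNA-centric, context-centric
    (boolean keyword) and disease-centric queries with aspect views and
    CSV/JSON export; and ships a seeded synthetic-abstract generator with
    gold annotations plus a precision/recall scorer so the whole pipeline
    is testable without any network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
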