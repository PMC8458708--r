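Package: icblenv
Title: Evidence Integration for Immune-Checkpoint Blockade Plus Lenvatinib
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Meta-analysis of objective response and disease control
    proportions across trial cohorts of immune-checkpoint blockade (ICB)
    combined with lenvatinib, using the Freeman-Tukey double-arcsine
    transform with DerSimonian-Laird heterogeneity and I-squared based
    model selection, together with rule-based multi-omics scoring stages
    (tumor versus normal target-gene expression, target-gene correlation,
    driver alteration frequency, immune-infiltration correlation and
    survival risk) and an integration step that flags tumor types carrying
    at least two positive treatment-related molecular characteristics.
    Includes seeded synthetic-data generators emulating TCGA-like inputs
    so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    MASS
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
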