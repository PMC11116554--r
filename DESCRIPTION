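Package: mpsuite
Title: Metabolic Pathway-Based Subtyping of Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Single-sample gene-set enrichment scoring of expression
    matrices with a kernel-CDF random-walk statistic, unsupervised
    discovery of metabolic pathway-based subtypes (MPS) by k-means with a
    consensus vote of cluster-validity indices, supervised subtype
    transfer across cohorts by nearest shrunken centroids, differential
    enrichment statistics, and a survival suite (Cox proportional
    hazards, Kaplan-Meier, nested risk-group models, multivariable risk
    scoring, sliding-threshold biomarker stratification). Includes a
    seeded synthetic-cohort generator with planted subtype structure and
    coupled survival so the whole pipeline is testable without external
    cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
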