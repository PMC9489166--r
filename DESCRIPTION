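Package: ddpp
Title: Digital Display Precision Predictor for Paired Tumor-Normal Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the Digital Display Precision Predictor (DDPP), a prognostic
    score for resected non-small-cell lung cancer built from differential gene
    expression between paired tumor and normal lung tissue. Gene weights
    (log2 fold-change times log-base-1.1 intensity) are screened against
    disease-free survival within histology-by-treatment groups, aggregated into
    per-group linear correlators, and clustered (exact 1-D k-means, k = 2) into
    high/low risk classes. Also provides an immune-checkpoint tolerance
    classifier for normal lung tissue (CTLA-4, PD-L1, ICOS), Kaplan-Meier,
    log-rank and Cox survival summaries, random-gene-set specificity and
    bootstrap signature-stability validation, and a seeded synthetic cohort
    generator emulating the study design for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
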