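Package: hamscore
Title: Gene Set Scoring and Cross-Dataset Analysis of Human Alzheimer's Microglia Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for cross-dataset analysis of microglial activation
    signatures in bulk, whole-tissue and single-cell/nucleus RNA-seq data.
    Implements control-centered gene set scores and signed differential
    expression (DE) scores on log-stabilized expression, myeloid balancing
    of whole-tissue cohorts to control for cell-composition confounding,
    pseudobulk aggregation from UMI count matrices with per-study QC
    presets, a per-gene linear-model DE stage with Cook's-distance outlier
    filtering and Benjamini-Hochberg adjustment, Fluidigm-style qPCR Ct
    processing with global-median delta-Ct normalization, cohort
    characteristic tables with exact tests, and a seeded synthetic-data
    generator emulating each input kind for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
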