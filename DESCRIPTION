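Package: patchseek
Title: Content-Based Retrieval and Molecular Association for Histology Image Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale engine for content-based retrieval of hematoxylin-and-eosin
    histology image patches and for linking tissue morphology to molecular readouts.
    Provides HSV-saturation tissue segmentation and fixed-grid patch extraction,
    a pluggable patch-encoder contract with unit-norm embeddings, gated-attention
    multiple-instance learning with multi-task mutation and gene-set-expression
    heads, compact vector indexes (exact, inverted-file product quantization, and
    iterative-quantization binary hashing) with mosaic subsampling, empirical
    significance scoring of retrieval hits, mAP at 5 retrieval evaluation
    protocols, and spatial-transcriptomics association statistics (Cohen's d,
    Wilcoxon rank-sum, Benjamini-Hochberg FDR, permutation gene-set enrichment).
    Ships seed-deterministic synthetic-data generators for every input class so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    methods,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    Matrix,
    jsonlite,
    png,
    EBImage,
    pROC
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
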