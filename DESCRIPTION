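Package: schptmbench
Title: Benchmarking Framework for Single-Cell Histone-Modification Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark imputation algorithms on single-cell
    histone post-translational modification (scHPTM) data such as sortChIC
    and scCUT&Tag. Provides a ground-truth-preserving simulator that builds
    cell-type pseudobulks from a labeled count matrix, adds uniform noise at
    a controlled signal-to-noise ratio and downsamples to a target read
    depth; a suite of embedding-free evaluation metrics (per-cell Pearson
    correlation to ground truth, Signal-in-Peaks, the SIMIC neighbor
    similarity ratio, KNN cell-type prediction, signal-enrichment
    metaprofiles); and a min-max scaling and ranking scheme that scores
    arbitrary imputed matrices per task and per scenario.
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
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    cluster,
    uwot,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
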