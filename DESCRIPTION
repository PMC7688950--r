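Package: tripnoise
Title: Chromosomal Position Effects on Reporter Expression Mean and Noise
Version: 1.0.0
Authors@R:
    person("Quantitative Reporter Screens", "Maintainers",
           email = "maintainers@example.org", role = c("aut", "cre"))
Description: A tested pipeline for barcoded-reporter (TRIP-style) screens of
    chromosomal position effects on gene expression mean and noise (CV2).
    Provides error-collapsing of sequencing barcodes by Hamming distance,
    combinatorial split-pool clone decoding, replicate-concordant integration
    site assignment, flow-cytometry gating and per-clone mean/CV2
    summarisation, chromatin feature extraction (windowed transcription-factor
    enrichment and nearest-distance to ChromHMM states), and a screened
    multivariate regression linking chromatin features to expression mean and
    noise. A seeded synthetic-data generator emulates every input with known
    ground truth so each stage is testable by recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
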