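Package: spotforge
Title: Preprocessing Toolkit for Array-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Technology-agnostic preprocessing of array-based spatial
    transcriptomics sequencing data: declarative barcode/UMI extraction from
    read pairs, poly(A) and adapter trimming, gene-function tagging of
    alignments with multimapper-aware read resolution, construction,
    cleaning, merging and downsampling of digital gene expression (DGE)
    matrices, hexagonal and Visium-style mesh aggregation of spatial units,
    tissue detection by connected high-UMI regions, barcode-complexity
    quality control with theoretical baselines, long-read library signature
    annotation by local alignment against an oligo building-block catalog,
    and registration of count-derived rasters to histology images by
    multiscale normalized cross-correlation. A seeded synthetic-data module
    generates fixtures with planted ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    igraph,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
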