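Package: nanowell
Type: Package
Title: Simulation and Analysis of Nanowell-Based Single-Cell RNA-Seq
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end toolkit for nanowell (microchip) single-cell RNA-seq
    with well barcodes and unique molecular identifiers (UMIs): a synthetic
    data generator with serialized ground truth (Poisson well occupancy,
    negative binomial expression, PCR duplication, sequencing errors,
    chimeric reads, ambient RNA, species mixtures, well images, dispenser
    checkerboard assays), image-based selection of single-cell wells via
    Laplacian-of-Gaussian blob detection, perfect-match barcode
    demultiplexing, UMI-cluster transcript counting with mismatch tolerance
    and read-support filtering, per-cell quality control and median-ratio
    normalization, sequencing-saturation downsampling, barnyard multiplet
    and purity estimation, hierarchical clustering with marker-based cell
    type labeling, and dispense-tip misalignment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    tiff,
    withr,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
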