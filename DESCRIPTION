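Package: trackseg
Title: Hypothesis-Free L0 and Fused-Lasso Segmentation of Epigenomic Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact penalized changepoint segmentation for epigenomic signal
    tracks. Approximates a noisy track by a piecewise-constant signal by
    minimizing a per-family reconstruction loss (Gaussian squared error,
    Poisson deviance for read counts, binomial deviance for dual-track
    methylation/coverage data) plus an L0 penalty on the number of
    changepoints, solved exactly by a functional-pruning dynamic program over
    piecewise convex envelopes in the natural parameter; an exact fused-lasso
    (L1) counterpart is provided for comparison. Includes binned ("offset")
    cross-validation for penalty selection on autocorrelated ChIP-seq-like
    tracks, readers and writers for BigWig, BedGraph, BED and bismark
    coverage formats, evaluation statistics for compressed representations
    (compression ratio, peak fold change, maximum Jaccard index, region
    enrichment, breakpoint-to-TES distance), and seeded synthetic-data
    generators so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
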