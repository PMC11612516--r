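Package: poolscan
Title: Pool-Seq Genome Scans and Interactome-Assisted Enrichment for
    Domestication Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting signatures of domestication from pooled
    whole-genome sequencing (Pool-Seq) of farmed and natural-origin
    populations. Implements read-depth representation simulations that
    justify minimum-depth thresholds, biallelic SNP calling from pooled
    per-position read counts, per-SNP differentiation scans (average
    cross-group FST, pooled Fisher exact tests, and a covariance-corrected
    XtX statistic) with Benjamini-Hochberg adjustment and consensus outlier
    classification, annotation of outlier SNPs to genes and CpG islands
    within a configurable window, and interactome-assisted candidate-gene
    enrichment with a degree-connectivity sweep, permutation null, and
    degree/radiality network topology indices. A synthetic-data generator
    with ground truth supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
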