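Package: replorg
Title: Replication-Biased Genome Organisation Analysis for Circular
    Multi-Origin Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how gene expression and genome-organisation
    features vary with distance to the nearest replication origin on
    circular chromosomes carrying several origins, as in Sulfolobus and
    other crenarchaea. Converts two-channel (cDNA versus genomic DNA)
    microarray spot tables into per-gene expression estimates, computes
    circular origin distances, coding density, divergently transcribed
    intergenic gaps, core-gene and transposon densities in sliding or
    non-overlapping windows, and tests distance gradients with rank
    correlations and rank-sum tests, including an expression-binned
    confound analysis and a closed-form gene-dosage null model for
    asynchronous exponentially growing populations. A synthetic-data
    module generates genomes and spot tables with known injected
    gradients so every pipeline stage can be verified against ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
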