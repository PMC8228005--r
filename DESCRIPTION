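Package: driftscan
Title: Selection-Signature Scans from SNP Genotypes via Smoothed FST
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case/control selection-signature analysis for SNP-array genotypes,
    as used to search for genomic regions linked to exterior defects such as
    capped hock in pig breeds. Reads and writes PLINK text and binary genotype
    filesets, applies a quality-control chain (per-variant missingness,
    Hardy-Weinberg exact test, genomic-relationship-based relatedness pruning,
    sliding-window LD pruning), computes population-structure diagnostics by
    eigendecomposition of the genomic relationship matrix, estimates per-SNP
    FST between two phenotype groups (Weir-Cockerham variance components or a
    pure-drift moment estimator), smooths the FST track over SNP windows,
    calls outlier regions above an empirical quantile, and annotates the
    resulting regions against user-supplied gene and QTL interval files with
    hypergeometric enrichment and Benjamini-Hochberg adjustment. A synthetic
    genotype generator under the Balding-Nichols pure-drift model, with
    planted differentiated windows, supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
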