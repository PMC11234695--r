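Package: coregQTL
Title: Multi-Layer Molecular QTL Co-Regulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking chromatin accessibility, histone-modification,
    gene-expression, and protein quantitative trait loci (caQTL, hQTL, eQTL,
    pQTL) at a locus. Implements input-normalised chromatin phenotypes from
    ChIP-seq/ATAC-seq count matrices, repeated-measures protein phenotypes,
    genomic-relationship-matrix construction, average-information REML
    heritability, mixed-linear-model single-variant association with
    leave-one-chromosome/segment-out designs and conditional scans, QTL
    effect-correlation and PCA pseudo-R2 co-localisation statistics,
    core-haplotype extraction, and allele-aware transcription-factor
    binding-site scanning with exact score-distribution p-values. A seeded
    synthetic-data generator emulates the causal cascade (regulatory variant
    to open chromatin to transcript to protein) in an F2 cross so the whole
    pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4,
    DESeq2,
    withr
Config/testthat/edition: 3
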