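Package: asepipe
Title: Allele-Specific Expression Analysis for Hybrid RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of allele-specific gene expression (ASE) in an
    F1 hybrid from RNA-seq alignments of the hybrid and its two inbred parents.
    Calls inter-parental transcriptome SNPs from quality-filtered exonic
    pileups (consensus, depth, site-quality and stage-concordance filters),
    counts parental alleles in hybrid reads at each SNP, tests allelic
    imbalance with an exact two-sided binomial test, aggregates SNP-level
    calls to transcript- and stage-level bias classifications, computes
    expression metrics (RPKM, fold coverage, log2 fold change with
    Benjamini-Hochberg FDR), summarises the SNP substitution spectrum with
    strand-complement collapsing, and classifies cis versus trans regulatory
    divergence by confronting parental expression ratios with hybrid allelic
    ratios. A synthetic-data module simulates aligned reads (SAM), reference
    sequence, annotation and ground-truth tables with planted SNPs, allelic
    fractions and regulatory modes, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    methods,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
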