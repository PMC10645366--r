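Package: u1apa
Title: Differential Expression and Alternative Polyadenylation Analysis
    for U1 snRNA Gene Knockouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of bulk RNA-seq from single U1 snRNA
    gene deletion strains: negative-binomial differential expression
    screening (fold-change > 2, FDR < 0.05), gene-feature enrichment by
    intron count, gene length, intron length and GC content, 3'-UTR
    alternative polyadenylation calling via a two-segment change-point
    estimator of the percentage of distal polyA-site usage (PDUI),
    5'-splice-site-like U1-binding-site scanning in windows around
    polyA sites, trans-splicing isoform quantification from
    isoform-specific junction reads, and qPCR delta-Ct validation
    arithmetic. Includes a seeded synthetic-data generator emulating a
    six-strain larval RNA-seq design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
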