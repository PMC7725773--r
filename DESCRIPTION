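Package: patcraft
Title: Periodic A/T Cluster Scoring and Silencing-Resistant Transgene Design
    for C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering transgenes that resist germline silencing in
    Caenorhabditis elegans. Scores Periodic An/Tn Clusters (PATCs) along DNA
    with a dynamic-programming chain model in classic and strand-balanced
    modes, computes codon adaptation indices and performs constrained
    synonymous recoding (restriction-motif and homopolymer avoidance, piRNA
    21U-RNA target-site depletion), plans and inserts introns under
    first-exon placement rules, simulates BsaI Golden-Gate intron exchange,
    and lints annotated constructs against eight germline-expression
    engineering rules. Includes seeded synthetic-sequence generators so every
    analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
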