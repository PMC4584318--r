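Package: alulandscape
Title: Alu Repeat Landscape Analysis of Candidate Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates Alu/SINE repeat elements in gene-region sequence
    sets and summarises their landscape: repeat density, coverage,
    orientation and GC statistics per region category (genes, CDS,
    introns, 5'UTRs, 3'UTRs); gene-set enrichment via Fisher exact and
    EASE scores with Bonferroni correction; detection of inverted Alu
    (IRAlu) pairs within 3'UTRs; and verification of dsRNA duplex
    formation by base-pair-maximisation folding and cofolding. Includes
    a seed-and-extend local-alignment repeat detector, a RepeatMasker
    .out reader, and a synthetic-data module that plants point-mutated,
    strand-randomised repeat copies into GC-controlled background
    sequence with exact ground truth, so the whole pipeline is testable
    end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
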