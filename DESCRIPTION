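Package: protomir
Title: Small RNA Sequencing Analysis of Plant miRNAs in Unreplicated Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing pipeline for comparing two
    unreplicated plant libraries (e.g. callus tissue versus freshly isolated
    protoplasts): adapter trimming with a per-category read-accounting ledger,
    hierarchical annotation of collapsed reads against ncRNA classes, a mature
    miRNA catalogue and genome gene models, novel miRNA discovery from hairpin
    precursor folding under plant miRNA criteria, differential expression
    calling with TPM normalisation and an exact conditional count test, and
    rule-based plant miRNA target prediction with G-U wobble weighting and a
    duplex minimum-free-energy ratio criterion. A fully ground-truthed
    synthetic data generator makes every stage testable without external
    downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
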