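Package: mirpost
Title: Post-Discovery Analysis of miRNA Deep-Sequencing and RT-qPCR Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis that follows miRNA discovery in
    a newly sequenced genome: validation and annotation of candidate hairpin
    precursors against miRBase-, Rfam- and genome-style BLAST evidence,
    detection of miRNA gene clusters from genomic coordinates, per-10^4
    normalization of mature miRNA read counts, screening and model-based
    ranking of candidate RT-qPCR reference genes (a NormFinder-style variance
    decomposition, including the best two-gene combination), and
    identification of tissue-enriched miRNAs from Ct data by the comparative
    Ct (delta-delta-Ct) method with Welch tests and Bonferroni control.
    Includes a seeded synthetic-data generator that emulates the multi-tissue
    study design (eight deep-sequencing libraries; nine tissues by eight
    individuals for qPCR) so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
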