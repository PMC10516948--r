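Package: cameta
Title: Core-Accessory Metatranscriptomics for Bacterial Pangenomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partitions a bacterial pangenome into core and accessory gene
    clusters, selects a best reference genome by competitive recruitment of
    metatranscriptomic reads, calls differentially expressed genes against a
    biotic control with a negative-binomial Wald test (Benjamini-Hochberg
    corrected, Cook's-distance outlier control), and projects the
    differential-expression signal onto the core/accessory partition to
    summarize where a population's transcriptional response lives
    (core-accessory metatranscriptome). Includes a synthetic-data generator
    producing pangenomes, read libraries and treatment-structured count
    matrices with known truth, and a command-line interface binding the
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
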