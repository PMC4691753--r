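Package: mirtailor
Title: MicroRNA 3'-Tailing, Absolute Quantification and Maternal
    Transcript Clearance Analysis for Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy pipeline for developmental small RNA sequencing studies:
    detection of nontemplated 3'-end nucleotide additions on mature
    microRNAs by iterative 3' trimming and remapping, multi-map-corrected
    microRNA counting with reads-per-million normalization, absolute
    microRNA quantification against spike-in or endogenous references,
    genomic clustering of microRNA loci and seed-family grouping,
    canonical seed-match (6mer/7mer-A1/7mer-m8/8mer) target prediction
    over merged 3' UTRs, and hypergeometric plus permutation
    target-enrichment statistics linking early-expressed microRNAs to
    maternal transcript clearance. Includes a fully specified synthetic
    data generator with a machine-readable truth record so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
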