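Package: cpxscan
Title: Detection and Analysis of Cytosine-Based Dinucleotide (CpX) Islands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CpG, CpA, CpT and CpC islands in genome sequences with a
    generalized Takai-Jones sliding-window algorithm (seed, jump-extension,
    rollback, alternating trim, gap merge), computes per-chromosome island
    statistics (count, covered bp, median length, frequency per kb, coverage
    percent), island shores, and overlap reports against annotation features
    with a permutation-based enrichment control. Includes a Markov-chain
    synthetic genome generator with planted islands so the full analysis is
    testable without any genome download, plus BED, BedGraph and CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    stringr,
    tidyr,
    ggplot2,
    generics,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
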