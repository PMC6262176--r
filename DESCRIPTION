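Package: screpmine
Title: Mining Secreted Cysteine-Rich Tandem-Repeat Proteins from Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects secreted cysteine-rich repeat proteins (SCREPs) in
    protein FASTA files by incremental-bisection self-alignment: each mature
    sequence is split at a sliding division site and the two segments are
    locally aligned under BLOSUM62 with affine gaps, so tandem domain repeats
    surface as high-scoring self-alignments. Candidate sets are then refined
    by cysteine-density profiling, annotation-driven exclusion of
    heme- and redox-cysteine protein classes, and greedy identity-threshold
    redundancy clustering; domain architectures are classified as pure or
    combinatorial repeats with a repeat-purity statistic; and candidates are
    screened against reference toxin sets using Karlin-Altschul bit scores
    and E-values. A deterministic synthetic-sequence generator provides
    positive and decoy benchmarks with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
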