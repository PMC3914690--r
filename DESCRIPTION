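Package: symdegen
Title: Comparative Analysis of Genome Degeneration in Nascent Bacterial
    Endosymbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the early stages of reductive genome
    evolution in host-restricted bacteria by comparison against a close
    free-living relative. Provides reference-anchored pseudogene
    classification with typing of inactivating mutations (frameshifts,
    premature stops, truncations, insertion-sequence interruptions),
    Nei-Gojobori dN/dS estimation with a relaxed-selection screen for
    cryptic pseudogenes, exact k-mer synteny block detection with
    replichore-symmetry classification of rearrangements, GC-skew and
    KOPS-motif chromosome architecture analysis including dif-site search,
    insertion-sequence annotation with a permutation test for intergenic
    clustering and detection of IS-bounded duplications, 16S rRNA
    stem-mutation classification, and a seeded genome-degeneration
    simulator that emits a replayable ground-truth event ledger for
    method validation.
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
    S4Vectors,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
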