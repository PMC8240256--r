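Package: rabsim
Title: Repeat-Associated Binding Site Discovery, Enrichment and Motif
    Maturation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies repeat-associated transcription-factor binding
    sites (RABS) by overlap-fraction classification of ChIP-seq peaks
    against RepeatMasker annotations, quantifies per-family transposable
    element enrichment against a TSS-anchored constrained-shuffle
    bootstrap null with an exact two-sided binomial test, scans IUPAC and
    log-odds motifs with spacing and density summaries, and models the
    maturation of imperfect proto-motifs in a SINE consensus into
    canonical circadian-regulator binding motifs via CpG-deamination-aware
    substitution paths and Kimura 2-parameter divergence. A synthetic-data
    generator simulates a SINE amplification burst with CpG-biased
    mutation, proximity-biased insertion, maturation-dependent peak calls
    and a sister-lineage split, with full ground truth, so every pipeline
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
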