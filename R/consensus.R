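# Built-in synthetic SINE consensus model.

# 160-nt synthetic consensus. The filler sequence was screened so that,
# besides the annotated windows, no window lies within one substitution of
# the optimal E-Box or RORE on either strand, and maturation of the 3' pair
# creates exactly two optimal E-Boxes 12 bp apart (start-to-start).
RSINE_LIKE_SEQ <- paste0(
  "TGAGGACGAG", "TGACCT", "GA", "AGTTCG",
  "CATGCTAGCGTGCGCTGCTGGATCTTTAAAGGCGTG", "AGGAGA",
  "CCCTTAATTATT", "CACATG",
  "GAGACTCAATCGACTAGTTTGTGCAAAAAGAGCTGTCCGAGCTAACGTACCA",
  "CACGCG", "TCTTCA", "CACGCG", "CAATCA"
)

#' Synthetic SINE consensus with circadian proto-motifs
#'
#' A 160-nt synthetic consensus emulating the proto-motif architecture of a
#' murine-specific SINE: a perfect antisense RORE closely followed by a
#' sense RORE two substitutions from optimal, a second imperfect sense RORE,
#' a central E-Box one (non-CpG) substitution from optimal, and — the
#' element's distinctive feature — a 3' pair of E-Boxes separated by 6 nt,
#' each one CpG-deamination (C->T) event away from the canonical CACGTG.
#' This is a synthetic stand-in, not a curated consensus from a repeat
#' database.
#'
#' @return A [consensus_model()].
#' @export
rsine_like_consensus <- function() {
  consensus_model(
    name = "RSINE-like (synthetic)",
    sequence = RSINE_LIKE_SEQ,
    proto_motifs = tibble::tibble(
      label = c("RORE 1", "RORE 2", "RORE 3",
                "E-Box 1", "E-Box 2", "E-Box 3"),
      offset = c(10L, 18L, 60L, 78L, 136L, 148L),
      strand = c("-", "+", "+", "+", "+", "+"),
      observed = c("AGGTCA", "AGTTCG", "AGGAGA",
                   "CACATG", "CACGCG", "CACGCG"),
      canonical = c("AGGTCA", "AGGTCA", "AGGTCA",
                    "CACGTG", "CACGTG", "CACGTG")
    )
  )
}

#' The canonical-perfecting substitution list for the synthetic consensus
#'
#' Maps every proto-motif label to its optimal target; applying it with
#' [evolve_consensus()] perfects all E-Box and RORE motifs (the already
#' perfect antisense RORE contributes no change).
#'
#' @return A named character vector suitable for [evolve_consensus()].
#' @export
perfecting_substitutions <- function() {
  c("RORE 1" = "AGGTCA", "RORE 2" = "AGGTCA", "RORE 3" = "AGGTCA",
    "E-Box 1" = "CACGTG", "E-Box 2" = "CACGTG", "E-Box 3" = "CACGTG")
}
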