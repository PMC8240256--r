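# Proto-motif annotation, CpG-deamination-aware substitution paths,
# in-silico consensus evolution, per-copy maturation calls, and Kimura
# 2-parameter divergence.
#
# A proto-motif is a near-match to a canonical TF binding motif carried by a
# TE consensus; "maturation" is the post-insertion substitution path that
# converts it into the canonical motif. The deamination channel (C->T at a
# CpG, or G->A as the minus-strand image of the same event) is flagged on
# every substitution because methyl-CpG deamination runs roughly an order
# of magnitude faster than other point mutations and is therefore the
# dominant route to motif gain.

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# Hamming distance of a window to a degenerate pattern: number of positions
# whose base is not allowed by the IUPAC letter.
iupac_mismatches <- function(window_chars, sets) {
  sum(!mapply(function(ch, s) ch %in% s, window_chars, sets))
}

#' Find imperfect (proto-)motifs in a consensus sequence
#'
#' Scans both strands for windows within `max_mismatch` substitutions of
#' each canonical motif. Exact matches are reported with distance 0.
#' Overlapping reports for distinct canonical motifs are all retained; for
#' palindromic motifs the duplicate minus-strand report of the same window
#' is collapsed.
#'
#' @param consensus A DNA string.
#' @param canonical_motifs Named character vector of IUPAC motifs
#'   (default: the optimal E-Box and RORE).
#' @param max_mismatch Maximum substitutions (default 2).
#' @return A tibble `motif`, `offset` (0-based, plus strand), `strand`,
#'   `observed` (motif-oriented window), `canonical`, `mismatches`.
#' @export
find_proto_motifs <- function(consensus,
                              canonical_motifs = c(
                                "E-Box" = "CACGTG",
                                "RORE" = "AGGTCA"
                              ),
                              max_mismatch = 2L) {
  consensus <- toupper(consensus)
  ch <- strsplit(consensus, "")[[1]]
  n <- length(ch)
  rows <- list()
  for (m in seq_along(canonical_motifs)) {
    pat <- toupper(canonical_motifs[[m]])
    nm <- names(canonical_motifs)[m] %||% pat
    L <- nchar(pat)
    if (n < L) next
    strands <- if (is_palindromic(pat)) "+" else c("+", "-")
    for (st in strands) {
      sets <- iupac_sets(if (st == "+") pat else revcomp(pat))
      for (s in 0:(n - L)) {
        win <- ch[(s + 1):(s + L)]
        d <- iupac_mismatches(win, sets)
        if (d <= max_mismatch) {
          obs <- paste(win, collapse = "")
          rows[[length(rows) + 1]] <- tibble::tibble(
            motif = nm, offset = s, strand = st,
            observed = if (st == "+") obs else revcomp(obs),
            canonical = pat, mismatches = d
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(motif = character(), offset = integer(),
                          strand = character(), observed = character(),
                          canonical = character(), mismatches = integer()))
  }
  dplyr::arrange(out, .data$offset, .data$motif, .data$strand)
}

#' Minimal substitution path between two equal-length motif strings
#'
#' One event per mismatching position. Each event is classified as
#' deamination-consistent when, evaluated on the *source* (pre-mutation)
#' sequence with its flanking context, it is a C->T with the C immediately
#' followed by G, or a G->A with the G immediately preceded by C (the
#' minus-strand image of the same CpG deamination). Positions whose needed
#' neighbour is unknown (no flank supplied) are conservatively classified
#' non-consistent.
#'
#' @param observed Source string (e.g. a proto-motif).
#' @param canonical Target string of the same length.
#' @param flank5,flank3 Optional source-sequence context immediately
#'   before/after the motif window.
#' @return A tibble `position` (1-based within the motif), `from_base`,
#'   `to_base`, `deamination_consistent`.
#' @export
substitution_path <- function(observed, canonical, flank5 = "", flank3 = "") {
  observed <- toupper(observed)
  canonical <- toupper(canonical)
  if (nchar(observed) != nchar(canonical)) {
    stop("observed and canonical must have equal length ",
         "(gapped paths are out of scope)", call. = FALSE)
  }
  obs <- strsplit(observed, "")[[1]]
  can <- strsplit(canonical, "")[[1]]
  full <- strsplit(paste0(toupper(flank5), observed, toupper(flank3)), "")[[1]]
  off <- nchar(flank5)
  pos <- which(obs != can)
  tibble::tibble(
    position = pos,
    from_base = obs[pos],
    to_base = can[pos],
    deamination_consistent = vapply(pos, function(i) {
      from <- obs[i]
      to <- can[i]
      if (from == "C" && to == "T") {
        j <- off + i + 1
        j <= length(full) && full[j] == "G"
      } else if (from == "G" && to == "A") {
        j <- off + i - 1
        j >= 1 && full[j] == "C"
      } else {
        FALSE
      }
    }, logical(1))
  )
}

#' Construct a consensus model
#'
#' Bundles a consensus sequence with its labelled proto-motif annotation.
#'
#' @param name Model name.
#' @param sequence Consensus DNA string.
#' @param proto_motifs A tibble with columns `label`, `offset` (0-based),
#'   `strand`, `observed`, `canonical`.
#' @return An object of class `consensus_model`.
#' @export
consensus_model <- function(name, sequence, proto_motifs) {
  sequence <- toupper(sequence)
  stopifnot(all(c("label", "offset", "strand", "observed", "canonical")
                %in% names(proto_motifs)))
  L <- nchar(proto_motifs$observed)
  if (any(proto_motifs$offset < 0 |
          proto_motifs$offset + L > nchar(sequence))) {
    stop("proto-motif window outside consensus bounds", call. = FALSE)
  }
  # the annotation must agree with the sequence
  win <- substring(sequence, proto_motifs$offset + 1, proto_motifs$offset + L)
  oriented <- ifelse(proto_motifs$strand == "-", revcomp(win), win)
  if (!all(oriented == toupper(proto_motifs$observed))) {
    stop("proto-motif 'observed' strings do not match the sequence",
         call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 proto_motifs = tibble::as_tibble(proto_motifs)),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("<consensus_model>", x$name, "-", nchar(x$sequence), "bp,",
      nrow(x$proto_motifs), "proto-motifs\n")
  print(x$proto_motifs)
  invisible(x)
}

#' Evolve a consensus in silico by perfecting named proto-motifs
#'
#' Replaces each named proto-motif window with its canonical target, in
#' place and strand-aware; no other position changes. The substitution
#' count is the number of positions differing between the input and output
#' sequences.
#'
#' @param model A [consensus_model()].
#' @param substitutions Named character vector mapping proto-motif labels to
#'   their target canonical strings.
#' @return A list with `sequence` (the evolved consensus) and
#'   `n_substitutions`.
#' @export
evolve_consensus <- function(model, substitutions) {
  stopifnot(inherits(model, "consensus_model"))
  seq_chars <- strsplit(model$sequence, "")[[1]]
  pm <- model$proto_motifs
  for (lab in names(substitutions)) {
    row <- which(pm$label == lab)
    if (length(row) != 1) {
      stop("unknown proto-motif label: ", lab, call. = FALSE)
    }
    target <- toupper(substitutions[[lab]])
    if (nchar(target) != nchar(pm$observed[row])) {
      stop("target length mismatch for ", lab, call. = FALSE)
    }
    plus_target <- if (pm$strand[row] == "-") revcomp(target) else target
    idx <- (pm$offset[row] + 1):(pm$offset[row] + nchar(target))
    seq_chars[idx] <- strsplit(plus_target, "")[[1]]
  }
  evolved <- paste(seq_chars, collapse = "")
  list(sequence = evolved,
       n_substitutions = hamming(model$sequence, evolved))
}

#' Call proto-motif maturation in consensus-aligned copies
#'
#' Maps each proto-motif window of the consensus through the (optionally
#' gapped) alignment into each copy. A copy is matured for a motif when its
#' oriented window equals the canonical string exactly; copies with a gap
#' inside the window are flagged uncallable for that motif. Events are the
#' substitutions from the consensus proto-motif to the copy's window,
#' deamination-classified against the consensus context.
#'
#' @param copies A tibble with columns `copy_id` and `seq`, each `seq`
#'   aligned to `aligned_consensus` (same string length; `-` for gaps).
#' @param model A [consensus_model()].
#' @param aligned_consensus The consensus as it appears in the alignment
#'   (defaults to the ungapped model sequence).
#' @return A tibble `copy_id`, `label`, `callable`, `matured`, `n_events`,
#'   `n_deamination_events`, `events` (list-column of event tibbles).
#' @export
classify_maturation <- function(copies, model,
                                aligned_consensus = model$sequence) {
  stopifnot(inherits(model, "consensus_model"))
  aligned_consensus <- toupper(aligned_consensus)
  if (any(nchar(copies$seq) != nchar(aligned_consensus))) {
    stop("copy alignment length differs from the consensus alignment",
         call. = FALSE)
  }
  # alignment column of each ungapped consensus position
  cons_chars <- strsplit(aligned_consensus, "")[[1]]
  col_of <- which(cons_chars != "-")
  pm <- model$proto_motifs
  cons_plain <- strsplit(model$sequence, "")[[1]]
  rows <- vector("list", nrow(copies) * nrow(pm))
  k <- 0
  for (i in seq_len(nrow(copies))) {
    cp <- strsplit(toupper(copies$seq[i]), "")[[1]]
    for (r in seq_len(nrow(pm))) {
      L <- nchar(pm$observed[r])
      cols <- col_of[(pm$offset[r] + 1):(pm$offset[r] + L)]
      win <- cp[cols]
      k <- k + 1
      if (any(win == "-")) {
        rows[[k]] <- tibble::tibble(
          copy_id = copies$copy_id[i], label = pm$label[r],
          callable = FALSE, matured = NA, n_events = NA_integer_,
          n_deamination_events = NA_integer_,
          events = list(NULL)
        )
        next
      }
      win_plus <- paste(win, collapse = "")
      oriented <- if (pm$strand[r] == "-") revcomp(win_plus) else win_plus
      # consensus flanks (source context) in motif orientation
      f5_idx <- pm$offset[r]
      f3_idx <- pm$offset[r] + L + 1
      f5 <- if (f5_idx >= 1) cons_plain[f5_idx] else ""
      f3 <- if (f3_idx <= length(cons_plain)) cons_plain[f3_idx] else ""
      if (pm$strand[r] == "-") {
        tmp <- f5
        f5 <- if (nzchar(f3)) revcomp(f3) else ""
        f3 <- if (nzchar(tmp)) revcomp(tmp) else ""
      }
      ev <- substitution_path(pm$observed[r], oriented,
                              flank5 = f5, flank3 = f3)
      rows[[k]] <- tibble::tibble(
        copy_id = copies$copy_id[i], label = pm$label[r],
        callable = TRUE,
        matured = oriented == toupper(pm$canonical[r]),
        n_events = nrow(ev),
        n_deamination_events = sum(ev$deamination_consistent),
        events = list(ev)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Kimura 2-parameter divergence between two sequences
#'
#' Counts transition (`P`) and transversion (`Q`) proportions over ungapped
#' compared sites and applies the K2P correction
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`. When the correction is
#' undefined (saturated divergence) the result is flagged rather than
#' raising an error. Unaligned inputs are first aligned globally
#' (match +1, mismatch -1, gap -2).
#'
#' @param seq_a,seq_b DNA strings.
#' @param aligned If `TRUE` (default) the strings must have equal length and
#'   may contain `-` gaps, which are skipped pairwise.
#' @return A one-row tibble `P`, `Q`, `d`, `n_sites`, `defined`.
#' @export
k2p_divergence <- function(seq_a, seq_b, aligned = TRUE) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (!aligned) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE
      ),
      gapOpening = 0, gapExtension = 2
    )
    seq_a <- as.character(Biostrings::alignedPattern(al))
    seq_b <- as.character(Biostrings::alignedSubject(al))
  }
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n == 0) {
    return(tibble::tibble(P = NA_real_, Q = NA_real_, d = NA_real_,
                          n_sites = 0L, defined = FALSE))
  }
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(tibble::tibble(P = P, Q = Q, d = NA_real_, n_sites = n,
                          defined = FALSE))
  }
  tibble::tibble(P = P, Q = Q, d = -0.5 * log(w1 * sqrt(w2)),
                 n_sites = n, defined = TRUE)
}
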