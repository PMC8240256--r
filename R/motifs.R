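# IUPAC / log-odds motif scanning, hit merging, density profiles, spacing
# statistics, discriminative k-mer enrichment and the motif-gain fold change.
#
# Scoring model: an IUPAC column distributes probability uniformly over its
# allowed bases against a flat 0.25 background, so every base allowed at a
# column with k alternatives scores log2(4/k) bits and every disallowed base
# scores -Inf. All exact degenerate matches of a motif therefore share the
# motif's maximum attainable score.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_FROM <- "ACGTRYKMSWBDHVNacgtrykmswbdhvn"
IUPAC_TO   <- "TGCAYRMKSWVHDBNtgcayrmkswvhdbn"

#' Built-in circadian-regulator binding motifs
#'
#' The degenerate E-Box bound by CLOCK:BMAL1, the canonical (optimal) E-Box,
#' the RORE bound by RORs/REV-ERBs with its optimal and discriminative
#' variants, and the D-Box bound by PAR-bZIP factors.
#'
#' @return A named character vector of IUPAC strings.
#' @export
circadian_motifs <- function() {
  c("E-Box" = "CACRTG",
    "E-Box optimal" = "CACGTG",
    "RORE" = "RGGTCA",
    "RORE optimal" = "AGGTCA",
    "RORE discriminative" = "AGGKCA",
    "D-Box" = "TTATGYAA")
}

#' Reverse complement of a DNA or IUPAC string
#'
#' @param x Character vector of sequences over the IUPAC alphabet.
#' @return The reverse complement(s).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr(IUPAC_FROM, IUPAC_TO, s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_iupac <- function(motif) {
  letters <- strsplit(toupper(motif), "")[[1]]
  if (length(letters) == 0 || !all(letters %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC motif: ", motif, call. = FALSE)
  }
  letters
}

resolve_motif <- function(motif) {
  built_in <- circadian_motifs()
  if (length(motif) == 1 && motif %in% names(built_in)) {
    stats::setNames(unname(built_in[motif]), motif)
  } else {
    nm <- names(motif) %||% unname(motif)
    stats::setNames(toupper(unname(motif)), nm)
  }
}

iupac_sets <- function(motif) IUPAC_SETS[check_iupac(motif)]

# Maximum attainable log-odds score of an IUPAC motif (bits).
iupac_top_score <- function(motif) {
  sum(vapply(iupac_sets(motif), function(s) log2(4 / length(s)), numeric(1)))
}

is_palindromic <- function(motif) {
  m <- unname(toupper(motif))
  identical(m, revcomp(m))
}

as_seq_set <- function(sequence) {
  s <- toupper(as.character(sequence))
  nm <- names(sequence) %||% if (length(s) == 1) "seq" else paste0("seq", seq_along(s))
  stats::setNames(s, nm)
}

empty_hits <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), motif = character(), score = numeric(),
                 is_top_score = logical())
}

# Start positions (0-based) of exact degenerate matches of `letters`
# (list of allowed-base sets is derived here) in one sequence.
match_starts <- function(seq_chars, sets) {
  L <- length(sets)
  n <- length(seq_chars)
  if (n < L) return(integer())
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    ok <- ok & seq_chars[j:(n - L + j)] %in% sets[[j]]
  }
  which(ok) - 1L
}

#' Scan sequences for exact degenerate (IUPAC) motif matches
#'
#' Every window matching the degenerate pattern is reported. Minus-strand
#' hits are reported in plus-strand coordinates with strand `"-"`. Windows
#' containing `N` never match. For palindromic motifs the redundant
#' minus-strand self-hits are collapsed to the plus strand.
#'
#' @param sequence A (optionally named) character vector of DNA sequences;
#'   names become the `chrom` column of the hits.
#' @param motif A single IUPAC string, or the name of one of
#'   [circadian_motifs()].
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return A hits tibble: `chrom`, `start` (0-based), `end`, `strand`,
#'   `motif`, `score` (log-odds bits), `is_top_score`.
#' @export
scan_iupac <- function(sequence, motif, both_strands = TRUE) {
  motif <- resolve_motif(motif)
  seqs <- as_seq_set(sequence)
  fwd_sets <- iupac_sets(motif)
  top <- iupac_top_score(motif)
  palin <- is_palindromic(motif)
  rev_sets <- if (both_strands && !palin) iupac_sets(revcomp(motif)) else NULL
  L <- length(fwd_sets)
  res <- lapply(names(seqs), function(id) {
    ch <- strsplit(seqs[[id]], "")[[1]]
    starts <- match_starts(ch, fwd_sets)
    strands <- rep("+", length(starts))
    if (!is.null(rev_sets)) {
      mstarts <- match_starts(ch, rev_sets)
      starts <- c(starts, mstarts)
      strands <- c(strands, rep("-", length(mstarts)))
    }
    if (length(starts) == 0) return(NULL)
    ord <- order(starts, strands)
    tibble::tibble(chrom = id, start = starts[ord],
                   end = starts[ord] + L, strand = strands[ord])
  })
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0) return(empty_hits())
  res$motif <- names(motif)
  res$score <- top
  res$is_top_score <- TRUE
  res
}

# Exact null distribution of the window score under an i.i.d. uniform
# background: returns a data.frame of finite scores with their tail
# probabilities P(S >= s). Columns contribute log2(4/k) with probability
# k/4 and -Inf otherwise.
score_null <- function(sets) {
  scores <- 0
  probs <- 1
  for (s in sets) {
    k <- length(s)
    v <- log2(4 / k)
    scores <- scores + v        # every allowed base shares one column score
    probs <- probs * (k / 4)
  }
  # one finite total for pure IUPAC columns; kept general via the caller
  data.frame(score = scores, prob = probs)
}

# General DP over per-column (score, prob) distributions, for probability
# matrices. `cols` is a list of data.frames with columns score, prob
# (finite entries only; missing mass is the -Inf miss channel).
convolve_score_null <- function(cols) {
  acc <- data.frame(score = 0, prob = 1)
  for (col in cols) {
    grid <- expand.grid(a = seq_len(nrow(acc)), b = seq_len(nrow(col)))
    score <- round(acc$score[grid$a] + col$score[grid$b], 9)
    prob <- acc$prob[grid$a] * col$prob[grid$b]
    agg <- stats::aggregate(prob, by = list(score = score), FUN = sum)
    acc <- data.frame(score = agg$score, prob = agg$x)
  }
  acc[order(-acc$score), , drop = FALSE]
}

#' Scan with an exact p-value threshold on the log-odds score
#'
#' Reports windows whose score has null probability at most `p_threshold`
#' under an i.i.d. uniform-background model. The score-to-p map is exact,
#' computed by dynamic programming over the per-column score distributions.
#' At the motif's maximum score this coincides with [scan_iupac()]; at
#' `p_threshold = 1` every window (including non-matching ones, score
#' `-Inf`) is reported.
#'
#' @inheritParams scan_iupac
#' @param p_threshold Null tail probability cutoff (default 0.01).
#' @return A hits tibble as in [scan_iupac()] plus a `p_value` column.
#' @export
threshold_scan <- function(sequence, motif, p_threshold = 0.01,
                           both_strands = TRUE) {
  motif <- resolve_motif(motif)
  letters <- check_iupac(motif)
  if (length(letters) > 16) {
    stop("motif longer than 16 nt: exact score null not tractable",
         call. = FALSE)
  }
  sets <- iupac_sets(motif)
  cols <- lapply(sets, function(s) {
    data.frame(score = log2(4 / length(s)), prob = length(s) / 4)
  })
  null <- convolve_score_null(cols)
  null$tail <- cumsum(null$prob)
  p_of_score <- function(s) {
    if (!is.finite(s)) return(1)
    i <- which(null$score <= s + 1e-9)
    if (length(i) == 0) return(1)
    null$tail[i[1]]
  }
  seqs <- as_seq_set(sequence)
  L <- length(sets)
  top <- iupac_top_score(motif)
  palin <- is_palindromic(motif)
  # score every window on each strand
  window_scores <- function(ch, sets_use) {
    n <- length(ch)
    if (n < L) return(numeric())
    sc <- rep(0, n - L + 1L)
    for (j in seq_len(L)) {
      s <- sets_use[[j]]
      v <- log2(4 / length(s))
      hitj <- ch[j:(n - L + j)] %in% s
      isn <- ch[j:(n - L + j)] == "N"
      sc <- sc + ifelse(isn, NA_real_, ifelse(hitj, v, -Inf))
    }
    sc
  }
  res <- lapply(names(seqs), function(id) {
    ch <- strsplit(seqs[[id]], "")[[1]]
    rows <- list()
    sc_f <- window_scores(ch, sets)
    strands <- c("+", if (both_strands && !palin) "-")
    for (st in strands) {
      sc <- if (st == "+") sc_f else window_scores(ch, iupac_sets(revcomp(motif)))
      if (length(sc) == 0) next
      # vectorized score -> p lookup over the few distinct finite scores
      pv <- rep(1, length(sc))
      fin <- which(is.finite(sc))
      if (length(fin) > 0) {
        uniq <- unique(sc[fin])
        pu <- vapply(uniq, p_of_score, numeric(1))
        pv[fin] <- pu[match(sc[fin], uniq)]
      }
      keep <- which(!is.na(sc) & pv <= p_threshold)
      if (length(keep) == 0) next
      rows[[st]] <- tibble::tibble(chrom = id, start = keep - 1L,
                                   end = keep - 1L + L, strand = st,
                                   motif = names(motif), score = sc[keep],
                                   is_top_score = sc[keep] >= top - 1e-9,
                                   p_value = pv[keep])
    }
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- empty_hits()
    out$p_value <- numeric()
    return(out)
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
}

#' Merge overlapping motif hits, averaging their scores
#'
#' Maximal chains of transitively overlapping hits (per sequence and motif)
#' collapse to one merged region spanning their union, scored with the
#' arithmetic mean of the member scores.
#'
#' @param hits A hits tibble from [scan_iupac()] or [threshold_scan()].
#' @return A tibble `chrom`, `start`, `end`, `motif`, `score`, `n_members`.
#' @export
merge_hits <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), motif = character(),
                          score = numeric(), n_members = integer()))
  }
  if (!"motif" %in% names(hits)) hits$motif <- "motif"
  groups <- dplyr::group_split(dplyr::group_by(hits, .data$chrom, .data$motif))
  out <- lapply(groups, function(g) {
    ir <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    tibble::tibble(
      chrom = g$chrom[1],
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      motif = g$motif[1],
      score = vapply(revmap, function(i) mean(g$score[i]), numeric(1)),
      n_members = lengths(revmap)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Score-weighted motif density profile around region centers
#'
#' Each region contributes a window of `2 * flank + 1` positions anchored at
#' its center, orientation-normalized (minus-strand regions are flipped).
#' The profile value at offset `o` is the mean, over regions, of the summed
#' score of merged hits covering position `center + o`. Regions whose
#' window is truncated by a sequence end contribute only their covered
#' offsets (masked positions drop out of the mean's denominator).
#'
#' @param regions Interval tibble (with optional `strand`).
#' @param merged_hits Output of [merge_hits()] on the same coordinate system.
#' @param flank Half-window in bp (default 100).
#' @param chrom_sizes Optional chrom-sizes tibble used to mask truncated
#'   windows.
#' @return An object of class `rabs_density_profile`: a tibble `motif`,
#'   `offset` (-flank..flank), `value`.
#' @export
density_profile <- function(regions, merged_hits, flank = 100L,
                            chrom_sizes = NULL) {
  if (nrow(regions) == 0) stop("regions must be non-empty", call. = FALSE)
  offsets <- seq(-flank, flank)
  centers <- (regions$start + regions$end) %/% 2L
  minus <- if ("strand" %in% names(regions)) regions$strand == "-" else
    rep(FALSE, nrow(regions))
  sizes <- if (!is.null(chrom_sizes)) chrom_sizes_lookup(chrom_sizes) else NULL
  motifs_present <- unique(merged_hits$motif)
  if (length(motifs_present) == 0) motifs_present <- "motif"
  out <- lapply(motifs_present, function(m) {
    mh <- merged_hits[merged_hits$motif == m, , drop = FALSE]
    acc <- rep(0, length(offsets))
    denom <- rep(0, length(offsets))
    for (i in seq_len(nrow(regions))) {
      ctr <- centers[i]
      pos <- ctr + offsets      # genomic position of each offset
      valid <- pos >= 0
      if (!is.null(sizes)) valid <- valid & pos < sizes[[regions$chrom[i]]]
      vals <- rep(0, length(offsets))
      hit_rows <- which(mh$chrom == regions$chrom[i] &
                          mh$start < ctr + flank + 1L & mh$end > ctr - flank)
      for (j in hit_rows) {
        cov <- pos >= mh$start[j] & pos < mh$end[j]
        vals[cov] <- vals[cov] + mh$score[j]
      }
      if (minus[i]) {
        vals <- rev(vals)
        valid <- rev(valid)
      }
      acc <- acc + ifelse(valid, vals, 0)
      denom <- denom + valid
    }
    tibble::tibble(motif = m, offset = offsets,
                   value = ifelse(denom > 0, acc / denom, 0))
  })
  structure(dplyr::bind_rows(out),
            class = c("rabs_density_profile", class(tibble::tibble())),
            flank = flank, n_regions = nrow(regions))
}

#' Start-to-start spacing to the nearest non-overlapping motif hit
#'
#' For each retained hit (by default only hits at the motif's maximum
#' attainable score), the start-to-start distance to the nearest other
#' retained hit that does not overlap it; distances are pooled across
#' sequences. Sequences with fewer than two retained hits contribute
#' nothing.
#'
#' @param hits A hits tibble.
#' @param top_score_only Retain only maximum-score hits (default `TRUE`).
#' @return A numeric vector of spacings in bp.
#' @export
nearest_motif_spacing <- function(hits, top_score_only = TRUE) {
  if (top_score_only && "is_top_score" %in% names(hits)) {
    hits <- hits[hits$is_top_score, , drop = FALSE]
  }
  if (nrow(hits) == 0) return(numeric())
  unlist(lapply(split(hits, hits$chrom), function(g) {
    n <- nrow(g)
    if (n < 2) return(numeric())
    vapply(seq_len(n), function(i) {
      non_ov <- which(g$end <= g$start[i] | g$start >= g$end[i])
      if (length(non_ov) == 0) return(NA_real_)
      min(abs(g$start[non_ov] - g$start[i]))
    }, numeric(1))
  }), use.names = FALSE) |> stats::na.omit() |> as.numeric()
}

#' Discriminative k-mer enrichment between two sequence sets
#'
#' For every k-mer observed in either set (collapsed with its reverse
#' complement), the fraction of foreground vs background sequences
#' containing it, the fold ratio and a one-sided exact hypergeometric
#' p-value for enrichment in the foreground. This is the discriminative
#' motif-discovery step: on sequence sets differing by motif maturation it
#' ranks the discriminating motifs first.
#'
#' @param foreground,background Character vectors of DNA sequences.
#' @param k K-mer length (at most 8).
#' @return A tibble `kmer`, `fg_fraction`, `bg_fraction`, `fold`, `p_value`,
#'   sorted by ascending p.
#' @export
kmer_enrichment <- function(foreground, background, k = 6L) {
  if (k > 8) stop("k must be <= 8", call. = FALSE)
  fg <- as_seq_set(foreground)
  bg <- as_seq_set(background)
  if (length(fg) == 0 || length(bg) == 0) {
    stop("both sequence sets must be non-empty", call. = FALSE)
  }
  if (min(nchar(c(fg, bg))) < k) {
    stop("k exceeds the shortest sequence length", call. = FALSE)
  }
  seq_kmers <- function(s) {
    n <- nchar(s)
    km <- substring(s, 1:(n - k + 1), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    if (length(km) == 0) return(character())
    unique(pmin(km, revcomp(km)))   # canonical form, presence per sequence
  }
  fg_counts <- table(unlist(lapply(fg, seq_kmers), use.names = FALSE))
  bg_counts <- table(unlist(lapply(bg, seq_kmers), use.names = FALSE))
  kmers <- union(names(fg_counts), names(bg_counts))
  x_fg <- as.integer(ifelse(is.na(fg_counts[kmers]), 0, fg_counts[kmers]))
  x_bg <- as.integer(ifelse(is.na(bg_counts[kmers]), 0, bg_counts[kmers]))
  n_fg <- length(fg)
  n_bg <- length(bg)
  p <- stats::phyper(x_fg - 1, x_fg + x_bg, n_fg + n_bg - x_fg - x_bg, n_fg,
                     lower.tail = FALSE)
  out <- tibble::tibble(
    kmer = kmers,
    fg_fraction = x_fg / n_fg,
    bg_fraction = x_bg / n_bg,
    fold = ifelse(x_bg > 0, (x_fg / n_fg) / (x_bg / n_bg),
                  ifelse(x_fg > 0, Inf, NA_real_)),
    p_value = p
  )
  dplyr::arrange(out, .data$p_value, dplyr::desc(.data$fold))
}

#' Motif-gain fold change between bound and unbound sequence sets
#'
#' The per-sequence mean motif-hit count in the bound set divided by the
#' per-sequence mean in the unbound set. Applied independently to each
#' species' ortholog set, this quantifies lineage-specific motif gain.
#'
#' @param bound_seqs,unbound_seqs Character vectors of DNA sequences.
#' @param motif IUPAC motif (string or built-in name).
#' @return A one-row tibble: `fold` (`Inf` with `unbound_zero = TRUE` when
#'   the unbound set carries no hit), `mean_bound`, `mean_unbound`,
#'   `unbound_zero`.
#' @export
motif_gain_fold_change <- function(bound_seqs, unbound_seqs, motif) {
  if (length(bound_seqs) == 0 || length(unbound_seqs) == 0) {
    stop("both sequence sets must be non-empty", call. = FALSE)
  }
  count_hits <- function(seqs) {
    seqs <- as_seq_set(seqs)
    names(seqs) <- paste0("s", seq_along(seqs))
    h <- scan_iupac(seqs, motif)
    cnt <- table(factor(h$chrom, levels = names(seqs)))
    as.numeric(cnt)
  }
  mb <- mean(count_hits(bound_seqs))
  mu <- mean(count_hits(unbound_seqs))
  tibble::tibble(
    fold = if (mu > 0) mb / mu else if (mb > 0) Inf else NA_real_,
    mean_bound = mb,
    mean_unbound = mu,
    unbound_zero = mu == 0
  )
}
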