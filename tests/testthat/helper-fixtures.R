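# Shared fixture builders. All fixtures are generated in code.

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             chrom_len = 1e5, max_width = 500) {
  ci <- sample.int(length(chroms), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i) {
    sample.int(chrom_len - w[i], 1)
  }, numeric(1))
  tibble::tibble(chrom = chroms[ci], start = as.integer(s),
                 end = as.integer(s + w))
}

random_repeats <- function(n, families = c("A", "B", "C"), ...) {
  x <- random_intervals(n, ...)
  x$strand <- sample(c("+", "-"), n, replace = TRUE)
  x$family <- sample(families, n, replace = TRUE)
  x$class_name <- "SINE"
  x$divergence_pct <- round(stats::runif(n, 0, 30), 1)
  x
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force per-base overlap classifier: for each peak, the repeat
# covering the most of its bases (ties -> leftmost repeat start), computed
# by literal base counting.
brute_classify <- function(peaks, repeats, min_fraction = 0.5) {
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    best_bp <- 0L
    best_start <- NA_integer_
    best_fam <- NA_character_
    for (j in seq_len(nrow(repeats))) {
      r <- repeats[j, ]
      if (r$chrom != p$chrom) next
      bases <- sum(seq(p$start, p$end - 1) >= r$start &
                     seq(p$start, p$end - 1) < r$end)
      if (bases > best_bp ||
          (bases == best_bp && bases > 0 &&
           !is.na(best_start) && r$start < best_start)) {
        best_bp <- bases
        best_start <- r$start
        best_fam <- r$family
      }
    }
    if (best_bp / (p$end - p$start) >= min_fraction) best_fam
    else NA_character_
  }, character(1))
}

# Brute-force gap distance between two intervals (0 when overlapping or
# book-ended).
brute_gap <- function(s1, e1, s2, e2) {
  if (s1 < e2 && s2 < e1) return(0)
  max(s2 - e1, s1 - e2)
}

# Brute-force IUPAC window matcher via regular expressions.
iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           K = "[GT]", M = "[AC]", S = "[CG]", W = "[AT]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste0(map[strsplit(toupper(motif), "")[[1]]], collapse = "")
}

brute_scan_starts <- function(sequence, motif) {
  pat <- paste0("(?=", iupac_regex(motif), ")")
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m) - 1L
}
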