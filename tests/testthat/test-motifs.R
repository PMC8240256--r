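test_that("scan_iupac reports degenerate matches with strand handling", {
  # palindromic exact self-match collapses to one plus-strand hit
  h <- scan_iupac("CACGTG", "E-Box optimal")
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0L)
  expect_equal(h$strand, "+")
  expect_true(h$is_top_score)

  # R matches A under the degenerate E-Box, not under the canonical one
  expect_equal(nrow(scan_iupac("CACATG", "E-Box")), 1)
  expect_equal(nrow(scan_iupac("CACATG", "E-Box optimal")), 0)

  # minus-strand reporting in plus coordinates
  h2 <- scan_iupac("TTTTGACCTTTT", "RORE optimal")   # revcomp(AGGTCA)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 3L)
  expect_equal(h2$end, 9L)

  # N never matches
  expect_equal(nrow(scan_iupac("CACNTG", "E-Box")), 0)
  expect_error(scan_iupac("ACGT", "CAXGTG"), "invalid IUPAC")
})

test_that("scan_iupac equals brute-force regex enumeration on random
           sequences", {
  set.seed(5)
  motifs <- c("RGGTCA", "CACRTG", "TTATGYAA", "CACGTG")
  for (rep_i in 1:6) {
    s <- random_dna(3000)
    for (m in motifs) {
      hits <- scan_iupac(s, m)
      plus <- sort(brute_scan_starts(s, m))
      minus <- sort(brute_scan_starts(s, revcomp(m)))
      if (identical(toupper(m), revcomp(m))) {
        expect_equal(sort(hits$start), plus)
      } else {
        expect_equal(sort(hits$start[hits$strand == "+"]), plus)
        expect_equal(sort(hits$start[hits$strand == "-"]), minus)
      }
    }
  }
})

test_that("scanning the reverse complement mirrors hits", {
  set.seed(6)
  for (rep_i in 1:4) {
    s <- random_dna(1500)
    rc <- revcomp(s)
    m <- "RGGTCA"
    fwd <- scan_iupac(s, m)
    rev <- scan_iupac(rc, m)
    L <- nchar(m)
    mirrored <- sort(nchar(s) - rev$end)
    expect_equal(sort(fwd$start), mirrored)
    # strands swap
    expect_equal(sum(fwd$strand == "+"), sum(rev$strand == "-"))
    expect_equal(sum(fwd$strand == "-"), sum(rev$strand == "+"))
  }
})

test_that("threshold_scan is exact-scan at the top score and vacuous at
           p = 1", {
  set.seed(7)
  s <- random_dna(4000)
  m <- "CACRTG"
  exact <- scan_iupac(s, m)
  # at default p = 0.01 the only windows beating the null are exact matches
  th <- threshold_scan(s, m, p_threshold = 0.01)
  expect_equal(sort(th$start), sort(exact$start))
  expect_true(all(th$is_top_score))
  # vacuous threshold reports every (N-free) window on both strands
  th1 <- threshold_scan(s, m, p_threshold = 1)
  expect_equal(nrow(th1), 2 * (nchar(s) - nchar(m) + 1))
  expect_true(all(th1$p_value <= 1))
})

test_that("threshold_scan hit density matches the closed-form match
           probability", {
  set.seed(8)
  n <- 3e5
  s <- random_dna(n)
  hits <- threshold_scan(s, "CACGTG", p_threshold = 0.01)
  # palindromic: collapsed plus-strand reporting; expected density
  # (1/4)^6 per strandless window, doubled for both strands then halved
  # by palindrome collapse -> (1/4)^6 per window
  expected <- (n - 5) * (1 / 4)^6
  se <- sqrt(expected)
  expect_lt(abs(nrow(hits) - expected), 3 * se + 1)
})

test_that("merge_hits unions overlapping chains and averages scores", {
  h <- tibble::tibble(chrom = "s", start = c(0L, 3L), end = c(6L, 9L),
                      strand = "+", motif = "m", score = c(4, 8),
                      is_top_score = TRUE)
  m <- merge_hits(h)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 9L)
  expect_equal(m$score, 6)
  expect_equal(m$n_members, 2L)

  # disjoint hits are untouched
  h2 <- dplyr::mutate(h, start = c(0L, 20L), end = c(6L, 26L))
  m2 <- merge_hits(h2)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$score, c(4, 8))

  # transitive chain of three
  h3 <- tibble::tibble(chrom = "s", start = c(0L, 4L, 8L),
                       end = c(6L, 10L, 14L), strand = "+", motif = "m",
                       score = c(3, 6, 9), is_top_score = TRUE)
  m3 <- merge_hits(h3)
  expect_equal(m3$n_members, 3L)
  expect_equal(m3$score, 6)
})

test_that("merged hits are pairwise disjoint and conserve members", {
  set.seed(9)
  for (rep_i in 1:5) {
    s <- random_dna(5000)
    hits <- threshold_scan(s, "RGGTCA", p_threshold = 1)
    hits <- hits[sample.int(nrow(hits), 300), ]
    m <- merge_hits(hits)
    expect_equal(sum(m$n_members), nrow(hits))
    m <- dplyr::arrange(m, start)
    if (nrow(m) > 1) {
      expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
    }
  }
})

test_that("density_profile obeys delta, linearity and empty-signal cases", {
  regions <- tibble::tibble(chrom = c("chr1", "chr1"),
                            start = c(1000L, 5000L),
                            end = c(1200L, 5200L), strand = "+")
  empty <- merge_hits(tibble::tibble(chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     motif = character(), score = numeric(),
                                     is_top_score = logical()))
  prof0 <- density_profile(regions, empty, flank = 50)
  expect_true(all(prof0$value == 0))
  expect_equal(nrow(prof0), 101)

  # single hit of score s covering the first region's center
  hit <- tibble::tibble(chrom = "chr1", start = 1097L, end = 1103L,
                        motif = "m", score = 5, n_members = 1L)
  prof1 <- density_profile(regions[1, ], hit, flank = 50)
  expect_equal(prof1$value[prof1$offset == 0], 5)
  expect_equal(sum(prof1$value > 0), 6)
  # two regions, hit in one -> exactly half the single-region profile
  prof2 <- density_profile(regions, hit, flank = 50)
  expect_equal(prof2$value, prof1$value / 2)
  # region order is irrelevant
  prof3 <- density_profile(regions[2:1, ], hit, flank = 50)
  expect_equal(prof3$value, prof2$value)
})

test_that("minus-strand regions flip the profile orientation", {
  region_plus <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1200L,
                                strand = "+")
  region_minus <- dplyr::mutate(region_plus, strand = "-")
  hit <- tibble::tibble(chrom = "chr1", start = 1110L, end = 1116L,
                        motif = "m", score = 2, n_members = 1L)
  p_plus <- density_profile(region_plus, hit, flank = 30)
  p_minus <- density_profile(region_minus, hit, flank = 30)
  expect_equal(p_plus$value, rev(p_minus$value))
})

test_that("nearest_motif_spacing is start-to-start among non-overlapping
           hits", {
  # two 6-mers separated by a 6-nt gap: spacing 12
  h <- tibble::tibble(chrom = "s", start = c(0L, 12L), end = c(6L, 18L),
                      strand = "+", motif = "m", score = 1,
                      is_top_score = TRUE)
  expect_equal(nearest_motif_spacing(h), c(12, 12))
  # one hit: nothing
  expect_equal(length(nearest_motif_spacing(h[1, ])), 0)
  # three equally spaced
  h3 <- tibble::tibble(chrom = "s", start = c(0L, 12L, 24L),
                       end = c(6L, 18L, 30L), strand = "+", motif = "m",
                       score = 1, is_top_score = TRUE)
  expect_equal(nearest_motif_spacing(h3), c(12, 12, 12))
  # overlapping neighbours are skipped in favour of the nearest
  # non-overlapping hit
  h4 <- tibble::tibble(chrom = "s", start = c(0L, 3L, 20L),
                       end = c(6L, 9L, 26L), strand = "+", motif = "m",
                       score = 1, is_top_score = TRUE)
  expect_equal(nearest_motif_spacing(h4), c(20, 17, 17))
  # non-top hits are dropped by default
  h5 <- dplyr::mutate(h3, is_top_score = c(TRUE, FALSE, TRUE))
  expect_equal(nearest_motif_spacing(h5), c(24, 24))
})

test_that("kmer_enrichment separates planted foregrounds", {
  set.seed(10)
  bg_seqs <- vapply(1:60, function(i) random_dna(80), character(1))
  fg_seqs <- vapply(bg_seqs[1:60], function(s) {
    paste0(substr(s, 1, 40), "CACGTG", substr(s, 47, 80))
  }, character(1), USE.NAMES = FALSE)
  tab <- kmer_enrichment(fg_seqs, bg_seqs, k = 6)
  expect_equal(tab$kmer[1], "CACGTG")
  expect_equal(tab$fg_fraction[1], 1)
  expect_lt(tab$p_value[1], 1e-10)

  # identical sets: no discrimination
  null_tab <- kmer_enrichment(bg_seqs, bg_seqs, k = 6)
  expect_true(all(null_tab$fold == 1))
  expect_true(all(null_tab$p_value > 0.2))

  expect_error(kmer_enrichment(fg_seqs, bg_seqs, k = 9), "<= 8")
  expect_error(kmer_enrichment("ACG", bg_seqs, k = 6), "shortest")
})

test_that("kmer_enrichment p-values equal the exact contingency test", {
  set.seed(12)
  fg <- c(replicate(50, paste0(random_dna(30), "TTGACA", random_dna(30))),
          replicate(50, random_dna(66)))
  bg <- c(replicate(5, paste0(random_dna(30), "TTGACA", random_dna(30))),
          replicate(95, random_dna(66)))
  tab <- kmer_enrichment(fg, bg, k = 6)
  row <- tab[tab$kmer == pmin("TTGACA", revcomp("TTGACA")), ]
  x_fg <- round(row$fg_fraction * 100)
  x_bg <- round(row$bg_fraction * 100)
  oracle <- stats::fisher.test(
    matrix(c(x_fg, 100 - x_fg, x_bg, 100 - x_bg), nrow = 2),
    alternative = "greater"
  )$p.value
  expect_equal(row$p_value, oracle, tolerance = 1e-9)
  expect_gt(row$fold, 5)
  expect_lt(row$p_value, 1e-6)
})

test_that("motif_gain_fold_change counts per-sequence mean hits", {
  seqs <- vapply(1:10, function(i) random_dna(50), character(1))
  with_motif <- paste0(seqs, "CACGTG")
  expect_equal(motif_gain_fold_change(with_motif, with_motif,
                                      "E-Box optimal")$fold, 1)
  # bound each with exactly 1 E-Box; unbound: 1 of 10 sequences has one
  set.seed(14)
  clean <- vapply(1:10, function(i) {
    s <- random_dna(50)
    while (nrow(scan_iupac(s, "E-Box optimal")) > 0) s <- random_dna(50)
    s
  }, character(1))
  bound <- paste0(clean, "CACGTG")
  unbound <- c(paste0(clean[1], "CACGTG"), clean[2:10])
  res <- motif_gain_fold_change(bound, unbound, "E-Box optimal")
  expect_equal(res$fold, 10)
  # no hits in unbound: infinity sentinel with a flag, not an error
  res_inf <- motif_gain_fold_change(bound, clean, "E-Box optimal")
  expect_true(is.infinite(res_inf$fold))
  expect_true(res_inf$unbound_zero)
})
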