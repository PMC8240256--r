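test_that("find_proto_motifs reports near-matches with Hamming distance", {
  # CpG-path E-Box proto-motif at distance 1
  s1 <- paste0("TTTTTT", "CACGCG", "TTTTTT")
  pm1 <- find_proto_motifs(s1, c("E-Box" = "CACGTG"), max_mismatch = 1)
  expect_equal(nrow(pm1), 1)
  expect_equal(pm1$offset, 6L)
  expect_equal(pm1$mismatches, 1L)
  expect_equal(pm1$observed, "CACGCG")

  # non-CpG path: CACATG is one A->G from optimal
  s2 <- paste0("TTTTTT", "CACATG", "TTTTTT")
  pm2 <- find_proto_motifs(s2, c("E-Box" = "CACGTG"), max_mismatch = 1)
  expect_equal(nrow(pm2), 1)
  expect_equal(pm2$mismatches, 1L)

  # exact matches flagged distance 0
  pm0 <- find_proto_motifs("AACACGTGAA", c("E-Box" = "CACGTG"))
  expect_true(any(pm0$mismatches == 0))

  # brute-force oracle: every reported window is within the bound and no
  # in-bound window is missed
  set.seed(15)
  for (rep_i in 1:4) {
    s <- random_dna(300)
    pm <- find_proto_motifs(s, c("E-Box" = "CACGTG", "RORE" = "AGGTCA"),
                            max_mismatch = 2)
    chars <- strsplit(s, "")[[1]]
    for (motif in c("CACGTG", "AGGTCA")) {
      pats <- if (identical(motif, revcomp(motif))) {
        list(c("+", motif))
      } else {
        list(c("+", motif), c("-", revcomp(motif)))
      }
      for (p in pats) {
        mm <- vapply(0:(300 - 6), function(o) {
          sum(chars[(o + 1):(o + 6)] != strsplit(p[2], "")[[1]])
        }, numeric(1))
        found <- pm$offset[pm$strand == p[1] &
                             pm$canonical == ifelse(motif == "CACGTG",
                                                    "CACGTG", "AGGTCA")]
        expect_setequal(which(mm <= 2) - 1L, found)
      }
    }
  }
})

test_that("substitution_path classifies CpG deamination strand-aware", {
  # single C->T at a CpG (the C is followed by G within the motif)
  ev <- substitution_path("CACGCG", "CACGTG")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$position, 5L)
  expect_equal(ev$from_base, "C")
  expect_equal(ev$to_base, "T")
  expect_true(ev$deamination_consistent)

  # two strand-aware deaminations: G->A after C, then C->T before G
  ev2 <- substitution_path("CGCGCG", "CACGTG")
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$position, c(2L, 5L))
  expect_equal(ev2$from_base, c("G", "C"))
  expect_equal(ev2$to_base, c("A", "T"))
  expect_true(all(ev2$deamination_consistent))

  # identity
  expect_equal(nrow(substitution_path("CACGTG", "CACGTG")), 0)
  # event count equals the Hamming distance
  set.seed(16)
  for (rep_i in 1:10) {
    a <- random_dna(12)
    b <- random_dna(12)
    expect_equal(nrow(substitution_path(a, b)),
                 sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  }
  expect_error(substitution_path("ACGT", "ACG"), "equal length")
})

test_that("deamination classification is strand-symmetric", {
  set.seed(17)
  for (rep_i in 1:10) {
    a <- random_dna(10)
    b <- random_dna(10)
    f5 <- random_dna(1)
    f3 <- random_dna(1)
    fwd <- substitution_path(a, b, flank5 = f5, flank3 = f3)
    rev <- substitution_path(revcomp(a), revcomp(b),
                             flank5 = revcomp(f3), flank3 = revcomp(f5))
    # mirrored positions, same classification
    fwd_o <- fwd[order(fwd$position), ]
    rev_o <- rev[order(-rev$position), ]
    expect_equal(11L - rev_o$position, fwd_o$position)
    expect_equal(rev_o$deamination_consistent, fwd_o$deamination_consistent)
  }
})

test_that("flank context gates deamination calls conservatively", {
  # C->T at the last motif position: consistent only if the next base (in
  # the flank) is G; unknown flank is conservative
  expect_true(substitution_path("AAC", "AAT",
                                flank3 = "G")$deamination_consistent)
  expect_false(substitution_path("AAC", "AAT",
                                 flank3 = "A")$deamination_consistent)
  expect_false(substitution_path("AAC", "AAT")$deamination_consistent)
  expect_true(substitution_path("GAA", "AAA",
                                flank5 = "C")$deamination_consistent)
  expect_false(substitution_path("GAA", "AAA")$deamination_consistent)
})

test_that("evolve_consensus perfects the annotated motifs in 7 nt", {
  model <- rsine_like_consensus()
  ev <- evolve_consensus(model, perfecting_substitutions())
  expect_equal(ev$n_substitutions, 7L)
  # every targeted motif now scans as canonical
  expect_equal(sort(scan_iupac(ev$sequence, "E-Box optimal")$start),
               c(78L, 136L, 148L))
  rore <- scan_iupac(ev$sequence, "RORE optimal")
  expect_setequal(rore$start, c(10L, 18L, 60L))
  # idempotence
  model2 <- consensus_model("evolved", ev$sequence,
                            dplyr::mutate(model$proto_motifs,
                                          observed = canonical))
  ev2 <- evolve_consensus(model2, perfecting_substitutions())
  expect_equal(ev2$n_substitutions, 0L)
  expect_identical(ev2$sequence, ev$sequence)
  # empty substitution list: unchanged
  ev0 <- evolve_consensus(model, stats::setNames(character(), character()))
  expect_identical(ev0$sequence, model$sequence)
  expect_equal(ev0$n_substitutions, 0L)
  # already-canonical motif contributes nothing
  ev1 <- evolve_consensus(model, c("RORE 1" = "AGGTCA"))
  expect_equal(ev1$n_substitutions, 0L)
  expect_error(evolve_consensus(model, c("E-Box 9" = "CACGTG")), "E-Box 9")
})

test_that("classify_maturation calls matured motifs through alignments", {
  model <- rsine_like_consensus()
  cons <- model$sequence
  # identity copy: nothing matured, no events
  calls <- classify_maturation(
    tibble::tibble(copy_id = "c1", seq = cons), model)
  expect_true(all(calls$callable))
  # no events anywhere; only the already-canonical antisense RORE reads as
  # "matured" (distance-0 proto-motif, trivially equal to canonical)
  expect_true(all(calls$n_events == 0))
  expect_equal(calls$label[calls$matured], "RORE 1")

  # C->T at both E-Box 2 and E-Box 3 (motif position 5 = offset + 4)
  chars <- strsplit(cons, "")[[1]]
  chars[136 + 5] <- "T"
  chars[148 + 5] <- "T"
  mat <- paste(chars, collapse = "")
  calls2 <- classify_maturation(
    tibble::tibble(copy_id = "c2", seq = mat), model)
  eboxes <- calls2[calls2$label %in% c("E-Box 2", "E-Box 3"), ]
  expect_true(all(eboxes$matured))
  expect_equal(eboxes$n_events, c(1L, 1L))
  expect_equal(eboxes$n_deamination_events, c(1L, 1L))
  expect_true(all(!calls2$matured[!calls2$label %in%
                                    c("E-Box 2", "E-Box 3", "RORE 1")]))

  # a deletion spanning E-Box 2 makes it uncallable, others callable
  gap_copy <- chars
  gap_copy[(136 + 1):(136 + 6)] <- "-"
  calls3 <- classify_maturation(
    tibble::tibble(copy_id = "c3", seq = paste(gap_copy, collapse = "")),
    model)
  expect_false(calls3$callable[calls3$label == "E-Box 2"])
  expect_true(is.na(calls3$matured[calls3$label == "E-Box 2"]))
  expect_true(all(calls3$callable[calls3$label != "E-Box 2"]))

  # gapped consensus alignment maps columns correctly
  aligned_cons <- paste0(substr(cons, 1, 50), "---", substr(cons, 51, 160))
  aligned_copy <- paste0(substr(mat, 1, 50), "AAA", substr(mat, 51, 160))
  calls4 <- classify_maturation(
    tibble::tibble(copy_id = "c4", seq = aligned_copy), model,
    aligned_consensus = aligned_cons)
  e2 <- calls4[calls4$label == "E-Box 2", ]
  expect_true(e2$matured)

  expect_error(classify_maturation(
    tibble::tibble(copy_id = "c5", seq = "ACGT"), model), "length")
})

test_that("maturation_flags agrees with classify_maturation", {
  set.seed(18)
  model <- rsine_like_consensus()
  cfg <- simulation_config(n_te_copies = 150L, mu = 0.05, seed = 31)
  amp <- amplify_te(cfg)
  flags <- rabsim:::maturation_flags(amp$copies$seq, model)
  calls <- classify_maturation(amp$copies, model)
  for (lab in model$proto_motifs$label) {
    expect_equal(unname(flags[, lab]),
                 calls$matured[calls$label == lab])
  }
})

test_that("k2p_divergence matches the closed form and ape's K80", {
  # identical sequences
  r0 <- k2p_divergence(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_equal(r0$P, 0)
  expect_equal(r0$Q, 0)
  expect_equal(r0$d, 0)

  # constructed pair: exactly 10 transitions and 5 transversions in 100 nt
  a <- strsplit(strrep("A", 100), "")[[1]]
  b <- a
  b[1:10] <- "G"   # transitions (A<->G)
  b[11:15] <- "C"  # transversions (A<->C)
  r1 <- k2p_divergence(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(r1$P, 0.10)
  expect_equal(r1$Q, 0.05)
  expect_equal(r1$d, -0.5 * log(0.75 * sqrt(0.90)))

  # symmetry, and agreement with ape's K80 on random diverged pairs
  set.seed(19)
  for (rep_i in 1:6) {
    x <- random_dna(400)
    y_chars <- strsplit(x, "")[[1]]
    flip <- sample.int(400, 40)
    y_chars[flip] <- vapply(y_chars[flip], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    y <- paste(y_chars, collapse = "")
    r <- k2p_divergence(x, y)
    r_sym <- k2p_divergence(y, x)
    expect_equal(r$d, r_sym$d)
    bin <- ape::as.DNAbin(list(a = strsplit(tolower(x), "")[[1]],
                               b = strsplit(tolower(y), "")[[1]]))
    expect_equal(r$d, as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-9)
  }

  # gaps are skipped pairwise
  rg <- k2p_divergence("AC-GT", "ACCGT")
  expect_equal(rg$n_sites, 4L)
  expect_equal(rg$d, 0)

  # saturation flags rather than errors
  sat <- k2p_divergence(strrep("A", 50), strrep("G", 50))
  expect_false(sat$defined)
  expect_true(is.na(sat$d))
  # zero comparable sites
  none <- k2p_divergence("----", "ACGT")
  expect_equal(none$n_sites, 0L)
  expect_false(none$defined)
})

test_that("d is monotone in P at fixed Q over the defined domain", {
  q <- 0.05
  ps <- seq(0, 0.4, by = 0.05)
  ds <- -0.5 * log((1 - 2 * ps - q) * sqrt(1 - 2 * q))
  expect_true(all(diff(ds) > 0))
})

test_that("unaligned input is aligned before distance estimation", {
  set.seed(20)
  x <- random_dna(200)
  # deletion of 10 nt plus a few substitutions
  y_chars <- strsplit(x, "")[[1]][-(50:59)]
  y_chars[c(5, 100, 150)] <- vapply(y_chars[c(5, 100, 150)], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  y <- paste(y_chars, collapse = "")
  r <- k2p_divergence(x, y, aligned = FALSE)
  expect_true(r$defined)
  expect_gte(r$n_sites, 185)
  expect_lt(r$d, 0.05)
  expect_gt(r$d, 0)
})

test_that("simulated burst divergence matches the analytic expectation", {
  # one-step mutation model at per-site rate mu with kappa = 1 (uniform
  # channel): expected P = mu/3 * ... actually uniform channel picks any
  # of 3 alternatives, 1/3 of which are transitions -> E[P] = mu/3,
  # E[Q] = 2mu/3; compare mean d to the K2P value at those proportions
  set.seed(21)
  mu <- 0.05
  cfg <- simulation_config(n_te_copies = 500L, mu = mu, kappa = 1,
                           cpg_channel = "uniform", seed = 77)
  amp <- amplify_te(cfg)
  cons <- cfg$consensus$sequence
  ds <- vapply(amp$copies$seq, function(s) k2p_divergence(cons, s)$d,
               numeric(1), USE.NAMES = FALSE)
  p_exp <- mu / 3
  q_exp <- 2 * mu / 3
  d_exp <- -0.5 * log((1 - 2 * p_exp - q_exp) * sqrt(1 - 2 * q_exp))
  se <- stats::sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - d_exp), 3 * se)
  # star-phylogeny histogram is unimodal-ish and roughly symmetric
  expect_lt(abs(mean(ds) - stats::median(ds)), 3 * se)
})
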