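# Synthetic-data generator: genome, TSS set, ancestral binding sites, a
# SINE amplification burst (star phylogeny, CpG-biased mutation),
# proximity-biased insertion, maturation-dependent peak calls, and a
# sister-lineage split — with full ground truth.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a desk-scale model of a murine-specific SINE burst:
#' a two-chromosome 1.5-Mb genome, one focal family amplified from the
#' built-in synthetic consensus in a single burst (star phylogeny) at
#' per-site substitution probability `mu`, with CpG sites deaminating
#' (C->T / G->A) at `kappa` times the base rate; a fraction of insertions
#' lands near pre-existing (ancestral) regulator binding sites; copies
#' whose designated E-Box pair has matured can be bound and then emit a
#' ChIP-seq-like peak.
#'
#' @param chrom_lengths Chromosome lengths in bp.
#' @param n_tss Number of transcription start sites (anchors of the
#'   enrichment null); every chromosome receives at least one.
#' @param n_ancestral_sites Number of pre-existing bound sites; these always
#'   emit peaks (the Non-RABS population).
#' @param n_te_copies Number of focal-family copies in the burst.
#' @param te_family Focal family name.
#' @param other_families Named integer vector of control-family copy counts
#'   (placed uniformly, never bound).
#' @param other_family_length Length of control-family elements (bp).
#' @param mu Per-site substitution probability per copy over the burst.
#' @param kappa CpG deamination rate multiplier (>= 1; the literature-scale
#'   default is 10).
#' @param cpg_channel `"deamination"` (CpG hits become C->T / G->A) or
#'   `"uniform"` (CpG hits draw uniformly among the three alternatives).
#' @param proximity_bias Fraction of focal insertions placed within
#'   `proximity_window` of an ancestral site.
#' @param proximity_window Window for proximity-biased placement (bp).
#' @param bind_prob Baseline probability that a pair-matured copy is bound.
#' @param maturation_coupling Additive binding-probability boost for
#'   proximity-placed copies.
#' @param peak_width,ancestral_width Width of emitted peaks / ancestral
#'   sites (bp).
#' @param designated_pair Labels of the proto-motif pair whose joint
#'   maturation licenses binding.
#' @param target_enrichment Optional target observed/expected ratio for the
#'   focal family; achieved by planting the analytically required number of
#'   copies directly onto distinct ancestral sites. `NULL` disables
#'   planting.
#' @param min_fraction RABS threshold assumed by the planting arithmetic.
#' @param post_split_mu Named per-lineage post-split substitution
#'   probabilities, `c(mouse = ..., rat = ...)`.
#' @param loss_fraction Per-lineage probability that a copy's ortholog is
#'   lost (emulating failed ortholog mapping).
#' @param consensus A [consensus_model()].
#' @param seed Master integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(chrom_lengths = c(750000L, 750000L),
                              n_tss = 100L,
                              n_ancestral_sites = 150L,
                              n_te_copies = 2000L,
                              te_family = "RSINE1_like",
                              other_families = c(B1_like = 400L,
                                                 B2_like = 400L,
                                                 B4_like = 400L,
                                                 ID_like = 400L,
                                                 MIR_like = 400L),
                              other_family_length = 150L,
                              mu = 0.05,
                              kappa = 10,
                              cpg_channel = c("deamination", "uniform"),
                              proximity_bias = 0.3,
                              proximity_window = 10000L,
                              bind_prob = 0.3,
                              maturation_coupling = 0.5,
                              peak_width = 200L,
                              ancestral_width = 200L,
                              designated_pair = c("E-Box 2", "E-Box 3"),
                              target_enrichment = NULL,
                              min_fraction = 0.5,
                              post_split_mu = c(mouse = 0.02, rat = 0.02),
                              loss_fraction = 0.4,
                              consensus = rsine_like_consensus(),
                              seed = 1L) {
  cpg_channel <- match.arg(cpg_channel)
  probs <- c(mu = mu, proximity_bias = proximity_bias,
             bind_prob = bind_prob,
             maturation_coupling = maturation_coupling,
             loss_fraction = loss_fraction, post_split_mu)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (kappa < 1) stop("kappa must be >= 1", call. = FALSE)
  if (n_te_copies < 0 || any(other_families < 0)) {
    stop("copy counts must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(consensus, "consensus_model"))
  if (!all(designated_pair %in% consensus$proto_motifs$label)) {
    stop("designated_pair labels missing from the consensus model",
         call. = FALSE)
  }
  structure(list(
    chrom_lengths = as.numeric(chrom_lengths), n_tss = n_tss,
    n_ancestral_sites = n_ancestral_sites, n_te_copies = n_te_copies,
    te_family = te_family, other_families = other_families,
    other_family_length = other_family_length,
    mu = mu, kappa = kappa, cpg_channel = cpg_channel,
    proximity_bias = proximity_bias, proximity_window = proximity_window,
    bind_prob = bind_prob, maturation_coupling = maturation_coupling,
    peak_width = peak_width, ancestral_width = ancestral_width,
    designated_pair = designated_pair,
    target_enrichment = target_enrichment, min_fraction = min_fraction,
    post_split_mu = post_split_mu, loss_fraction = loss_fraction,
    consensus = consensus, seed = as.integer(seed)
  ), class = "simulation_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the background genome, TSS set and ancestral binding sites
#'
#' I.i.d. uniform background sequence; TSS placed uniformly per chromosome
#' (allocated proportionally to length, at least one each); ancestral sites
#' placed uniformly without mutual overlap at fixed width.
#'
#' @param config A [simulation_config()].
#' @return A list: `genome` (named character vector), `chrom_sizes`,
#'   `tss`, `ancestral_peaks` (tibbles).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_tss == 0 && config$n_te_copies > 0) {
    stop("n_tss = 0 with TE copies requested: the shuffle null would be ",
         "undefined", call. = FALSE)
  }
  total <- sum(config$chrom_lengths)
  feature_bp <- config$n_ancestral_sites * config$ancestral_width +
    config$n_te_copies * nchar(config$consensus$sequence) +
    sum(config$other_families) * config$other_family_length
  if (feature_bp > 0.6 * total) {
    stop("infeasible packing: features would cover >60% of the genome",
         call. = FALSE)
  }
  with_seed(child_seed(config$seed, 1L), {
    chroms <- paste0("chr", seq_along(config$chrom_lengths))
    genome <- stats::setNames(
      vapply(config$chrom_lengths, rand_dna, character(1)), chroms
    )
    chrom_sizes <- tibble::tibble(chrom = chroms,
                                  length = config$chrom_lengths)
    # TSS: one per chromosome, remainder proportional to length
    n_extra <- max(0L, config$n_tss - length(chroms))
    alloc <- rep(1L, length(chroms)) +
      as.integer(stats::rmultinom(1, n_extra,
                                  config$chrom_lengths / total))
    tss <- dplyr::bind_rows(lapply(seq_along(chroms), function(i) {
      pos <- sort(sample.int(config$chrom_lengths[i] - 1L, alloc[i]))
      tibble::tibble(chrom = chroms[i], start = pos, end = pos + 1L,
                     name = paste0("tss_", chroms[i], "_", seq_along(pos)),
                     score = 0, strand = sample(c("+", "-"), alloc[i],
                                                replace = TRUE))
    }))
    # ancestral sites: uniform, non-overlapping (vectorized rejection:
    # draw a batch, keep the non-clashing ones, redraw the remainder)
    w <- config$ancestral_width
    acc_chr <- character(0)
    acc_start <- numeric(0)
    need <- config$n_ancestral_sites
    for (a in 1:200) {
      if (need == 0) break
      ci <- sample.int(length(chroms), need, replace = TRUE,
                       prob = config$chrom_lengths / total)
      s <- vapply(ci, function(j) {
        sample.int(config$chrom_lengths[j] - w, 1)
      }, numeric(1))
      cand_chr <- c(acc_chr, chroms[ci])
      cand_start <- c(acc_start, s)
      keep_new <- rep(TRUE, need)
      for (chr in unique(chroms[ci])) {
        idx <- which(cand_chr == chr)
        ord <- idx[order(cand_start[idx])]
        gaps <- diff(cand_start[ord]) < w
        # drop any NEW site clashing with either sorted neighbour; the
        # surviving set stays pairwise >= w apart and accepted sites
        # (prefix of cand) are never dropped
        bad <- ord[c(FALSE, gaps) | c(gaps, FALSE)]
        bad <- bad[bad > length(acc_chr)]
        keep_new[bad - length(acc_chr)] <- FALSE
      }
      acc_chr <- c(acc_chr, chroms[ci][keep_new])
      acc_start <- c(acc_start, s[keep_new])
      need <- config$n_ancestral_sites - length(acc_chr)
    }
    if (need > 0) stop("infeasible packing of ancestral sites",
                       call. = FALSE)
    ancestral_peaks <- tibble::tibble(
      chrom = acc_chr, start = acc_start, end = acc_start + w,
      name = "", score = 0, strand = "*"
    )
    ancestral_peaks <- dplyr::arrange(ancestral_peaks, .data$chrom,
                                      .data$start)
    ancestral_peaks$start <- as.integer(ancestral_peaks$start)
    ancestral_peaks$end <- as.integer(ancestral_peaks$end)
    ancestral_peaks$name <- paste0("asite_", seq_len(nrow(ancestral_peaks)))
    list(genome = genome, chrom_sizes = chrom_sizes, tss = tss,
         ancestral_peaks = ancestral_peaks)
  })
}

# Mutate equal-length sequences, each from its own source, with CpG-aware
# rates: sites that are the C of a CpG (or its G) mutate at kappa * mu and,
# under the deamination channel, always to T (resp. A); other sites mutate
# at mu, uniformly to one of the three alternatives.
mutate_seqs <- function(seqs, mu, kappa, channel = "deamination") {
  if (length(seqs) == 0 || mu == 0) {
    return(list(seqs = seqs,
                mutations = tibble::tibble(seq_index = integer(),
                                           position = integer(),
                                           from = character(),
                                           to = character())))
  }
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L))
  m <- matrix(unlist(strsplit(seqs, "")), nrow = L)
  nxt <- rbind(m[-1, , drop = FALSE], "X")
  prv <- rbind("X", m[-L, , drop = FALSE])
  cpg_c <- m == "C" & nxt == "G"
  cpg_g <- m == "G" & prv == "C"
  rate <- matrix(mu, nrow = L, ncol = ncol(m))
  rate[cpg_c | cpg_g] <- min(1, kappa * mu)
  hit <- matrix(stats::runif(length(m)), nrow = L) < rate
  from <- m[hit]
  to <- character(length(from))
  if (channel == "deamination") {
    is_c <- cpg_c[hit]
    is_g <- cpg_g[hit]
    to[is_c] <- "T"
    to[is_g] <- "A"
    other <- !(is_c | is_g)
  } else {
    other <- rep(TRUE, length(from))
  }
  if (any(other)) {
    alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, sum(other), replace = TRUE)
    to[other] <- mapply(function(b, k) alts[[b]][k], from[other], pick)
  }
  m[hit] <- to
  idx <- which(hit, arr.ind = TRUE)
  list(
    seqs = apply(m, 2, paste, collapse = ""),
    mutations = tibble::tibble(seq_index = idx[, 2], position = idx[, 1],
                               from = from, to = to)
  )
}

#' Amplify the consensus into a burst of independently mutated copies
#'
#' Star phylogeny: every copy derives independently from the consensus.
#' Each site mutates with probability `mu`, multiplied by `kappa` at CpG
#' sites, where (under the deamination channel) the hit is realized as
#' C->T, or G->A for the minus-strand image.
#'
#' @param config A [simulation_config()].
#' @param n Number of copies (defaults to `config$n_te_copies`).
#' @return A list: `copies` (tibble `copy_id`, `seq`) and `mutations`
#'   (tibble `copy_id`, `position` 1-based, `from`, `to`).
#' @export
amplify_te <- function(config, n = config$n_te_copies) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(child_seed(config$seed, 2L), {
    src <- rep(config$consensus$sequence, n)
    res <- mutate_seqs(src, config$mu, config$kappa, config$cpg_channel)
    ids <- sprintf("%s_%04d", config$te_family, seq_len(n))
    list(
      copies = tibble::tibble(copy_id = ids, seq = unname(res$seqs)),
      mutations = tibble::tibble(copy_id = ids[res$mutations$seq_index],
                                 position = res$mutations$position,
                                 from = res$mutations$from,
                                 to = res$mutations$to)
    )
  })
}

# Fast vectorized maturation flags: for each proto-motif, whether each
# copy's (ungapped, consensus-coordinate) window equals the canonical
# string. Cross-checked against classify_maturation() in the tests.
maturation_flags <- function(seqs, model) {
  pm <- model$proto_motifs
  out <- matrix(FALSE, nrow = length(seqs), ncol = nrow(pm),
                dimnames = list(NULL, pm$label))
  for (r in seq_len(nrow(pm))) {
    L <- nchar(pm$observed[r])
    win <- substring(seqs, pm$offset[r] + 1, pm$offset[r] + L)
    if (pm$strand[r] == "-") win <- revcomp(win)
    out[, r] <- win == pm$canonical[r]
  }
  out
}

#' Place TE insertions on the simulated genome
#'
#' A `proximity_bias` fraction of focal copies is placed within
#' `proximity_window` of a random ancestral site but never overlapping one
#' ("near but not on"); the rest, and all control families, are placed
#' uniformly genome-wide with no avoidance, so chance overlap with peaks
#' matches the shuffle null.
#' When `config$target_enrichment` is set, the analytically required number
#' of focal copies is additionally planted centered on distinct ancestral
#' sites so that the focal observed/expected RABS ratio targets that value.
#'
#' @param copies Output of [amplify_te()] (`$copies`).
#' @param config A [simulation_config()].
#' @param genome Output of [simulate_genome()].
#' @return A list: `te_annotations` (repeat tibble with `name` = copy id)
#'   and `placement` (tibble `copy_id`, `placed_mode`, `proximal`).
#' @export
place_insertions <- function(copies, config, genome) {
  stopifnot(inherits(config, "simulation_config"))
  sizes <- genome$chrom_sizes
  anc <- genome$ancestral_peaks
  total <- sum(sizes$length)
  with_seed(child_seed(config$seed, 3L), {
    n <- nrow(copies)
    lens <- nchar(copies$seq)
    mode <- rep("uniform", n)
    # planting for a target enrichment ratio
    if (!is.null(config$target_enrichment)) {
      r <- config$target_enrichment
      wp <- config$ancestral_width
      h <- ceiling(wp * config$min_fraction)
      adm <- mean(lens) + wp - 2 * h + 1
      chance <- nrow(anc) * adm / total      # per-copy chance of RABS
      m <- round((r - 1) * n * chance)
      if (m > nrow(anc)) {
        stop("target_enrichment needs more plantable sites than exist",
             call. = FALSE)
      }
      if (m > 0) mode[sample.int(n, m)] <- "planted"
    }
    free <- which(mode == "uniform")
    n_prox <- round(config$proximity_bias * length(free))
    if (n_prox > 0) mode[sample(free, n_prox)] <- "proximal"

    chrom <- character(n)
    start <- numeric(n)
    size_of <- stats::setNames(sizes$length, sizes$chrom)
    anc_by_chrom <- split(anc, anc$chrom)
    overlaps_anc <- function(chr, s, e) {
      a <- anc_by_chrom[[chr]]
      !is.null(a) && any(s < a$end & e > a$start)
    }
    planted_sites <- sample.int(nrow(anc), sum(mode == "planted"))
    pi <- 0
    for (i in seq_len(n)) {
      if (mode[i] == "planted") {
        pi <- pi + 1
        site <- anc[planted_sites[pi], ]
        ctr <- (site$start + site$end) %/% 2
        chrom[i] <- site$chrom
        start[i] <- ctr - lens[i] %/% 2
        next
      }
      ok <- FALSE
      for (a in 1:200) {
        if (mode[i] == "proximal") {
          site <- anc[sample.int(nrow(anc), 1), ]
          ctr <- (site$start + site$end) %/% 2
          s <- ctr + sample.int(2L * config$proximity_window + 1L, 1) -
            config$proximity_window - 1L
          chr <- site$chrom
          # near but not on: proximity-placed copies never cover a site
          if (s < 0 || s + lens[i] > size_of[[chr]]) next
          if (overlaps_anc(chr, s, s + lens[i])) next
        } else {
          ci <- sample.int(nrow(sizes), 1, prob = sizes$length / total)
          chr <- sizes$chrom[ci]
          s <- sample.int(size_of[[chr]] - lens[i], 1)
        }
        chrom[i] <- chr
        start[i] <- s
        ok <- TRUE
        break
      }
      if (!ok) stop("packing failure placing insertion ", copies$copy_id[i],
                    call. = FALSE)
    }
    focal <- tibble::tibble(
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + lens),
      strand = sample(c("+", "-"), n, replace = TRUE),
      family = config$te_family, class_name = "SINE", group = "B4_like",
      divergence_pct = NA_real_, name = copies$copy_id
    )
    # control families: truly uniform, no avoidance
    others <- dplyr::bind_rows(lapply(names(config$other_families), function(f) {
      k <- config$other_families[[f]]
      if (k == 0) return(NULL)
      ci <- sample.int(nrow(sizes), k, replace = TRUE,
                       prob = sizes$length / total)
      s <- vapply(ci, function(j) {
        sample.int(sizes$length[j] - config$other_family_length, 1)
      }, numeric(1))
      tibble::tibble(
        chrom = sizes$chrom[ci], start = as.integer(s),
        end = as.integer(s + config$other_family_length),
        strand = sample(c("+", "-"), k, replace = TRUE),
        family = f, class_name = "SINE", group = "control",
        divergence_pct = stats::runif(k, 5, 25),
        name = sprintf("%s_%04d", f, seq_len(k))
      )
    }))
    list(
      te_annotations = dplyr::bind_rows(focal, others),
      placement = tibble::tibble(copy_id = copies$copy_id,
                                 placed_mode = mode,
                                 proximal = mode %in% c("proximal", "planted"))
    )
  })
}

#' Derive maturation-dependent peak calls and complete the ground truth
#'
#' A focal copy is bound iff its designated E-Box pair has matured and a
#' Bernoulli coupling draw succeeds, with probability `bind_prob` plus
#' `maturation_coupling` for proximity-placed copies. Bound copies emit a
#' peak centered on the copy; ancestral sites always emit peaks (the
#' Non-RABS population).
#'
#' @param copies Output of [amplify_te()] (`$copies`).
#' @param placement Output of [place_insertions()].
#' @param config A [simulation_config()].
#' @param genome Output of [simulate_genome()].
#' @return A list: `peaks` (interval tibble) and `truth` (one row per copy:
#'   coordinates, `placed_mode`, `proximal`, per-motif `matured_*` flags,
#'   `pair_matured`, `bound`, `lineage`).
#' @export
derive_peaks <- function(copies, placement, config, genome) {
  stopifnot(inherits(config, "simulation_config"))
  flags <- maturation_flags(copies$seq, config$consensus)
  pair <- rowSums(flags[, config$designated_pair, drop = FALSE]) ==
    length(config$designated_pair)
  ann <- placement$te_annotations
  place <- placement$placement
  focal_ann <- ann[match(copies$copy_id, ann$name), , drop = FALSE]
  with_seed(child_seed(config$seed, 4L), {
    p_bind <- pmin(1, config$bind_prob +
                     config$maturation_coupling * place$proximal)
    bound <- pair & stats::runif(nrow(copies)) < p_bind
    truth <- tibble::tibble(
      copy_id = copies$copy_id,
      chrom = focal_ann$chrom, start = focal_ann$start,
      end = focal_ann$end, strand = focal_ann$strand,
      placed_mode = place$placed_mode, proximal = place$proximal,
      pair_matured = pair, bound = bound, lineage = "ancestral"
    )
    mat_cols <- as.data.frame(flags)
    names(mat_cols) <- paste0("matured_", gsub("[^A-Za-z0-9]+", "_",
                                               colnames(flags)))
    truth <- dplyr::bind_cols(truth, tibble::as_tibble(mat_cols))
    w <- config$peak_width
    ctr <- (focal_ann$start + focal_ann$end) %/% 2
    copy_peaks <- tibble::tibble(
      chrom = focal_ann$chrom,
      start = as.integer(pmax(0, ctr - w %/% 2)),
      end = as.integer(pmax(0, ctr - w %/% 2) + w),
      name = paste0("peak_", copies$copy_id),
      score = 0, strand = "*"
    )[bound, , drop = FALSE]
    peaks <- dplyr::bind_rows(genome$ancestral_peaks, copy_peaks)
    peaks <- dplyr::arrange(peaks, .data$chrom, .data$start)
    list(peaks = peaks, truth = truth)
  })
}

#' Split the burst into two sister lineages with independent evolution
#'
#' Each copy spawns a mouse-like and a rat-like descendant that accumulate
#' independent post-split substitutions under the same CpG-aware scheme
#' (per-lineage rates from `config$post_split_mu`). A `loss_fraction` of
#' copies is dropped independently per lineage, emulating failed ortholog
#' mapping; the ortholog map links surviving pairs.
#'
#' @param copies Output of [amplify_te()] (`$copies`).
#' @param config A [simulation_config()].
#' @return A list: `mouse`, `rat` (tibbles `copy_id`, `seq` of surviving
#'   descendants) and `ortholog_map` (tibble `copy_id`, `in_mouse`,
#'   `in_rat`, `orthologous`).
#' @export
simulate_lineage_split <- function(copies, config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(child_seed(config$seed, 5L), {
    evolve <- function(mu) {
      mutate_seqs(copies$seq, mu, config$kappa, config$cpg_channel)$seqs
    }
    mouse_seq <- evolve(config$post_split_mu[["mouse"]])
    rat_seq <- evolve(config$post_split_mu[["rat"]])
    keep_mouse <- stats::runif(nrow(copies)) >= config$loss_fraction
    keep_rat <- stats::runif(nrow(copies)) >= config$loss_fraction
    list(
      mouse = tibble::tibble(copy_id = copies$copy_id,
                             seq = unname(mouse_seq))[keep_mouse, ],
      rat = tibble::tibble(copy_id = copies$copy_id,
                           seq = unname(rat_seq))[keep_rat, ],
      ortholog_map = tibble::tibble(
        copy_id = copies$copy_id,
        in_mouse = keep_mouse, in_rat = keep_rat,
        orthologous = keep_mouse & keep_rat
      )
    )
  })
}

#' Simulate a complete dataset, optionally writing it to disk
#'
#' Runs [simulate_genome()], [amplify_te()], [place_insertions()] and
#' [derive_peaks()] under one master seed. With `out_dir`, writes
#' genome/copies FASTA, TSS/peaks/ancestral-peaks BED, a RepeatMasker-style
#' annotation table, the truth table (TSV) and a reproducibility manifest
#' (JSON: config digest, seed, per-file md5).
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `rabs_simulation` with elements `genome`,
#'   `chrom_sizes`, `tss`, `ancestral_peaks`, `te_annotations`, `copies`,
#'   `mutations`, `peaks`, `truth`, `config`, and `files` when written.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- simulate_genome(config)
  amp <- amplify_te(config)
  placement <- place_insertions(amp$copies, config, genome)
  pk <- derive_peaks(amp$copies, placement, config, genome)
  # divergence of each focal copy from the consensus (percent mismatches)
  ann <- placement$te_annotations
  focal_idx <- match(amp$copies$copy_id, ann$name)
  cons <- config$consensus$sequence
  div <- vapply(amp$copies$seq, function(s) hamming(s, cons), numeric(1)) /
    nchar(cons) * 100
  ann$divergence_pct[focal_idx] <- round(unname(div), 1)
  out <- structure(list(
    genome = genome$genome, chrom_sizes = genome$chrom_sizes,
    tss = genome$tss, ancestral_peaks = genome$ancestral_peaks,
    te_annotations = ann, copies = amp$copies, mutations = amp$mutations,
    peaks = pk$peaks, truth = pk$truth, config = config
  ), class = "rabs_simulation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      genome = file.path(out_dir, "genome.fa"),
      chrom_sizes = file.path(out_dir, "genome.chrom.sizes"),
      tss = file.path(out_dir, "tss.bed"),
      ancestral_peaks = file.path(out_dir, "ancestral_peaks.bed"),
      te_annotations = file.path(out_dir, "repeats.tsv"),
      copies = file.path(out_dir, "copies.fa"),
      peaks = file.path(out_dir, "peaks.bed"),
      truth = file.path(out_dir, "truth.tsv")
    )
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$genome),
                                paths[["genome"]])
    utils::write.table(out$chrom_sizes, paths[["chrom_sizes"]], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_bed(out$tss, paths[["tss"]])
    write_bed(out$ancestral_peaks, paths[["ancestral_peaks"]])
    write_repeatmasker(out$te_annotations, paths[["te_annotations"]])
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(out$copies$seq,
                                               out$copies$copy_id)),
      paths[["copies"]]
    )
    write_bed(out$peaks, paths[["peaks"]])
    utils::write.table(out$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- list(
      seed = config$seed,
      n_te_copies = config$n_te_copies,
      mu = config$mu, kappa = config$kappa,
      cpg_channel = config$cpg_channel,
      proximity_bias = config$proximity_bias,
      files = as.list(tools::md5sum(unname(paths)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$files <- c(paths, manifest = file.path(out_dir, "manifest.json"))
  }
  out
}
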