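# Constrained-shuffle bootstrap null and the two-sided binomial enrichment
# test for per-family transposable-element overrepresentation among peaks.
#
# The shuffle preserves, for every element, (i) its chromosome (hence
# per-chromosome copy counts) and (ii) its signed start-offset to the
# nearest TSS: each element is re-anchored to a uniformly drawn TSS on the
# same chromosome while keeping that offset. These are exactly the two
# constraints the null is meant to hold fixed, so chance overlap with peaks
# is estimated conditional on the TSS-relative placement of the repeat
# complement.

#' Shuffle repeats preserving chromosome counts and TSS distance
#'
#' Each repeat records its signed offset from its start to the nearest TSS
#' on the same chromosome, is re-anchored to a uniformly drawn TSS on that
#' chromosome, and keeps the offset, its length, family and strand.
#' Placements exceeding chromosome bounds are redrawn up to `max_attempts`
#' times and then clamped to the boundary.
#'
#' @param repeats Repeat tibble (see [read_repeatmasker()]).
#' @param tss Tibble of TSS positions with columns `chrom`, `start`, `end`
#'   (point features: `end = start + 1`), optionally `strand`.
#' @param chrom_sizes Chrom-sizes tibble.
#' @param seed Integer seed.
#' @param max_attempts Redraw cap before clamping.
#' @return A tibble like `repeats` with shuffled `start`/`end` plus a
#'   logical `clamped` column marking boundary-clamped placements.
#' @export
constrained_shuffle <- function(repeats, tss, chrom_sizes, seed = 1L,
                                max_attempts = 100L) {
  sizes <- chrom_sizes_lookup(chrom_sizes)
  no_tss <- setdiff(unique(repeats$chrom), unique(tss$chrom))
  if (length(no_tss) > 0) {
    stop("chromosome(s) with repeats but no TSS: ",
         paste(no_tss, collapse = ", "), call. = FALSE)
  }
  out <- repeats
  out$clamped <- FALSE
  with_seed(seed, {
    for (chr in unique(repeats$chrom)) {
      idx <- which(repeats$chrom == chr)
      tpos <- sort(tss$start[tss$chrom == chr])
      len <- repeats$end[idx] - repeats$start[idx]
      # signed offset to the nearest TSS (ties -> the smaller position)
      if (length(tpos) == 1) {
        anchor0 <- rep(tpos, length(idx))
      } else {
        nearest <- findInterval(repeats$start[idx], tpos, all.inside = TRUE)
        right <- pmin(nearest + 1L, length(tpos))
        use_right <- abs(tpos[right] - repeats$start[idx]) <
          abs(tpos[nearest] - repeats$start[idx])
        anchor0 <- ifelse(use_right, tpos[right], tpos[nearest])
      }
      offset <- repeats$start[idx] - anchor0
      chrlen <- unname(sizes[[chr]])
      n <- length(idx)
      new_start <- rep(NA_real_, n)
      todo <- seq_len(n)
      for (a in seq_len(max_attempts)) {
        if (length(todo) == 0) break
        draw <- tpos[sample.int(length(tpos), length(todo), replace = TRUE)] +
          offset[todo]
        ok <- draw >= 0 & draw + len[todo] <= chrlen
        new_start[todo[ok]] <- draw[ok]
        if (any(!ok)) last_draw <- draw[!ok]
        todo <- todo[!ok]
      }
      if (length(todo) > 0) {
        new_start[todo] <- pmin(pmax(last_draw, 0), chrlen - len[todo])
        out$clamped[idx[todo]] <- TRUE
      }
      out$start[idx] <- as.integer(new_start)
      out$end[idx] <- as.integer(new_start + len)
    }
  })
  out
}

# Fast attribution counter used inside the bootstrap: number of distinct
# peaks RABS-attributed to each family, identical to tabulating
# classify_rabs()'s RABS labels (asserted in the tests) but without
# building the per-peak result table.
rabs_family_counts <- function(peaks, repeats, min_fraction = 0.5,
                               peaks_gr = NULL) {
  if (nrow(peaks) == 0 || nrow(repeats) == 0) return(integer())
  widths <- unique(peaks$end - peaks$start)
  if (length(widths) == 1) {
    # constant peak width: pure findInterval interval join, no S4 overhead
    w <- widths
    qh <- integer()
    sh <- integer()
    for (chr in unique(repeats$chrom)) {
      p_idx <- which(peaks$chrom == chr)
      if (length(p_idx) == 0) next
      r_idx <- which(repeats$chrom == chr)
      ord_p <- p_idx[order(peaks$start[p_idx])]
      pstart <- peaks$start[ord_p]
      rs <- repeats$start[r_idx]
      re <- repeats$end[r_idx]
      lo <- findInterval(rs - w, pstart) + 1L   # pstart > rs - w
      hi <- findInterval(re - 1L, pstart)       # pstart < re
      n_ov <- pmax(0L, hi - lo + 1L)
      if (sum(n_ov) == 0) next
      rep_i <- rep.int(r_idx, n_ov)
      peak_j <- ord_p[sequence(n_ov, from = lo)]
      qh <- c(qh, peak_j)
      sh <- c(sh, rep_i)
    }
    if (length(qh) == 0) return(integer())
  } else {
    if (is.null(peaks_gr)) peaks_gr <- tbl_to_gr(peaks)
    rg <- tbl_to_gr(repeats)
    ov <- GenomicRanges::findOverlaps(peaks_gr, rg, ignore.strand = TRUE)
    if (length(ov) == 0) return(integer())
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
  }
  ov_bp <- pmin(peaks$end[qh], repeats$end[sh]) -
    pmax(peaks$start[qh], repeats$start[sh])
  ord <- order(qh, -ov_bp, repeats$start[sh])
  keep <- !duplicated(qh[ord])
  qb <- qh[ord][keep]
  sb <- sh[ord][keep]
  ob <- ov_bp[ord][keep]
  is_rabs <- ob / (peaks$end[qb] - peaks$start[qb]) >= min_fraction
  tab <- table(repeats$family[sb[is_rabs]])
  stats::setNames(as.integer(tab), names(tab))
}

#' Bootstrap the expected per-family peak-overlap counts
#'
#' Repeats are re-shuffled `n_replicates` times with [constrained_shuffle()];
#' in each replicate the shuffled repeats are classified against the peaks
#' with [classify_rabs()] and the number of peaks attributed to each family
#' is recorded. Replicate seeds derive deterministically from `seed`.
#'
#' @param peaks Peak interval tibble.
#' @param repeats Repeat tibble.
#' @param tss TSS tibble.
#' @param chrom_sizes Chrom-sizes tibble.
#' @param n_replicates Number of bootstrap replicates (the study-scale
#'   default is 1000; tests and examples use fewer).
#' @param min_fraction RABS overlap threshold passed to [classify_rabs()].
#' @param seed Master integer seed.
#' @return A tibble with columns `family`, `expected_mean`, `expected_sd`
#'   (0 when `n_replicates` is 1).
#' @export
bootstrap_expected <- function(peaks, repeats, tss, chrom_sizes,
                               n_replicates = 1000L, min_fraction = 0.5,
                               seed = 1L) {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  fams <- sort(unique(repeats$family))
  counts <- matrix(0, nrow = n_replicates, ncol = length(fams),
                   dimnames = list(NULL, fams))
  peaks_gr <- tbl_to_gr(peaks)
  for (k in seq_len(n_replicates)) {
    shuf <- constrained_shuffle(repeats, tss, chrom_sizes,
                                seed = child_seed(seed, k))
    tab <- rabs_family_counts(peaks, shuf, min_fraction = min_fraction,
                              peaks_gr = peaks_gr)
    counts[k, names(tab)] <- as.numeric(tab)
  }
  tibble::tibble(
    family = fams,
    expected_mean = unname(colMeans(counts)),
    expected_sd = if (n_replicates == 1) {
      rep(0, length(fams))
    } else {
      unname(apply(counts, 2, stats::sd))
    }
  )
}

#' Exact two-sided binomial test of observed vs bootstrap-expected counts
#'
#' Tests `observed` successes in `n_trials` against the null success
#' probability `expected_mean / n_trials`. The default two-sided p-value is
#' the minimal-likelihood convention: the sum of all binomial point
#' probabilities not exceeding that of the observed count (the construction
#' used by [stats::binom.test()]). `method = "doubling"` instead doubles the
#' smaller tail (capped at 1).
#'
#' @param observed Observed count (integer, `0 <= observed <= n_trials`).
#' @param expected_mean Bootstrap mean count, in `[0, n_trials]`.
#' @param n_trials Number of trials (the number of peaks).
#' @param method `"minlik"` (default) or `"doubling"`.
#' @return The two-sided p-value.
#' @export
binomial_enrichment_test <- function(observed, expected_mean, n_trials,
                                     method = c("minlik", "doubling")) {
  method <- match.arg(method)
  if (expected_mean < 0 || expected_mean > n_trials) {
    stop("expected_mean must lie in [0, n_trials]", call. = FALSE)
  }
  if (observed < 0 || observed > n_trials) {
    stop("observed must lie in [0, n_trials]", call. = FALSE)
  }
  p0 <- expected_mean / n_trials
  if (p0 %in% c(0, 1)) {
    forced <- if (p0 == 0) 0 else n_trials
    return(if (observed == forced) 1 else 0)
  }
  if (method == "minlik") {
    stats::binom.test(observed, n_trials, p = p0,
                      alternative = "two.sided")$p.value
  } else {
    lower <- stats::pbinom(observed, n_trials, p0)
    upper <- stats::pbinom(observed - 1, n_trials, p0, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  }
}

#' Type-I calibration of the enrichment test under a uniform null
#'
#' Simulates datasets with no planted enrichment: peaks and all repeat
#' families placed uniformly at random (placement decoupled from family
#' identity), TSS uniform, then runs the full bootstrap + binomial
#' enrichment machinery on each dataset. Under a calibrated test about 5%
#' of family-level p-values fall below 0.05.
#'
#' Sizes default to a regime where per-family expected counts are large
#' enough (~30) for the exact binomial to be near-continuous while peak
#' attribution stays unsaturated.
#'
#' @param n_datasets Number of simulated datasets.
#' @param n_families Families per dataset (all exchangeable).
#' @param copies_per_family Copies per family.
#' @param n_peaks Peaks per dataset.
#' @param chrom_lengths Chromosome lengths.
#' @param n_tss TSS per dataset (uniform; split across chromosomes).
#' @param repeat_length,peak_width Element widths (bp).
#' @param n_replicates Bootstrap replicates per dataset.
#' @param min_fraction RABS threshold.
#' @param seed Master seed.
#' @return A tibble `dataset`, `family`, `observed`, `expected_mean`,
#'   `p_value`.
#' @export
null_calibration <- function(n_datasets = 200L, n_families = 20L,
                             copies_per_family = 400L, n_peaks = 3000L,
                             chrom_lengths = c(3e6, 3e6), n_tss = 200L,
                             repeat_length = 150L, peak_width = 200L,
                             n_replicates = 100L, min_fraction = 0.5,
                             seed = 1L) {
  chroms <- paste0("chr", seq_along(chrom_lengths))
  chrom_sizes <- tibble::tibble(chrom = chroms, length = chrom_lengths)
  total <- sum(chrom_lengths)
  unif_intervals <- function(n, width) {
    ci <- sample.int(length(chroms), n, replace = TRUE,
                     prob = chrom_lengths / total)
    s <- vapply(ci, function(j) {
      sample.int(chrom_lengths[j] - width, 1)
    }, numeric(1))
    tibble::tibble(chrom = chroms[ci], start = as.integer(s),
                   end = as.integer(s + width))
  }
  out <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    ds_seed <- child_seed(seed, 1000L + d)
    res <- with_seed(ds_seed, {
      peaks <- unif_intervals(n_peaks, peak_width)
      tss <- unif_intervals(n_tss, 1L)
      repeats <- unif_intervals(n_families * copies_per_family,
                                repeat_length)
      repeats$strand <- "*"
      repeats$family <- rep(sprintf("fam%02d", seq_len(n_families)),
                            each = copies_per_family)
      exp_tbl <- bootstrap_expected(peaks, repeats, tss, chrom_sizes,
                                    n_replicates = n_replicates,
                                    min_fraction = min_fraction,
                                    seed = child_seed(ds_seed, 1L))
      obs <- rabs_family_counts(peaks, repeats,
                                min_fraction = min_fraction)
      exp_tbl$observed <- as.integer(ifelse(is.na(obs[exp_tbl$family]), 0,
                                            obs[exp_tbl$family]))
      exp_tbl$p_value <- vapply(seq_len(nrow(exp_tbl)), function(i) {
        binomial_enrichment_test(exp_tbl$observed[i],
                                 exp_tbl$expected_mean[i], n_peaks)
      }, numeric(1))
      exp_tbl$dataset <- d
      exp_tbl
    })
    out[[d]] <- res
  }
  dplyr::bind_rows(out)[, c("dataset", "family", "observed",
                            "expected_mean", "p_value")]
}

#' Per-family enrichment of repeats among peaks
#'
#' For every repeat family: the observed number of distinct peaks attributed
#' to the family by [classify_rabs()], the bootstrap expectation under the
#' constrained-shuffle null, the observed/expected ratio, and an exact
#' two-sided binomial p-value with `n_trials` = number of peaks. Families
#' are flagged by the conventional `observed > count_filter` copy filter but
#' all families are reported with p-values regardless (a family can fail the
#' filter yet be significantly enriched).
#'
#' @inheritParams bootstrap_expected
#' @param count_filter Minimum observed copies for `passes_count_filter`
#'   (default 50).
#' @param method Two-sided p construction, see [binomial_enrichment_test()].
#' @return An object of class `rabs_enrichment`: a tibble sorted by
#'   descending ratio with columns `family`, `observed`, `expected_mean`,
#'   `expected_sd`, `ratio`, `p_value`, `passes_count_filter`, carrying the
#'   run parameters as attributes.
#' @export
enrichment_report <- function(peaks, repeats, tss, chrom_sizes,
                              n_replicates = 1000L, min_fraction = 0.5,
                              seed = 1L, count_filter = 50L,
                              method = "minlik") {
  calls <- classify_rabs(peaks, repeats, min_fraction = min_fraction)
  obs_tab <- table(calls$repeat_family[calls$label == "RABS"])
  exp_tbl <- bootstrap_expected(peaks, repeats, tss, chrom_sizes,
                                n_replicates = n_replicates,
                                min_fraction = min_fraction, seed = seed)
  n_peaks <- nrow(peaks)
  out <- exp_tbl
  out$observed <- as.integer(ifelse(is.na(obs_tab[out$family]), 0,
                                    obs_tab[out$family]))
  out$ratio <- ifelse(out$expected_mean > 0,
                      out$observed / out$expected_mean,
                      ifelse(out$observed > 0, Inf, NA_real_))
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    binomial_enrichment_test(out$observed[i], out$expected_mean[i], n_peaks,
                             method = method)
  }, numeric(1))
  out$passes_count_filter <- out$observed > count_filter
  out <- out[order(-out$ratio, out$p_value), c(
    "family", "observed", "expected_mean", "expected_sd", "ratio",
    "p_value", "passes_count_filter"
  )]
  structure(tibble::as_tibble(out),
            class = c("rabs_enrichment", class(tibble::tibble())),
            n_peaks = n_peaks, n_replicates = n_replicates,
            min_fraction = min_fraction, seed = seed,
            count_filter = count_filter)
}
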