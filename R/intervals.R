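# Genomic interval I/O and the RABS / Non-RABS overlap-fraction classifier.
#
# All coordinates are 0-based half-open (BED convention) in every tibble the
# package exposes; conversion to the 1-based closed convention happens only
# at the GenomicRanges boundary, internally.

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a tab-separated file with columns chromosome name and
#'   length in bp (no header).
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  if (any(x$length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (anyDuplicated(x$chrom)) stop("duplicate chromosome names", call. = FALSE)
  tibble::as_tibble(x)
}

#' Read a BED3+ file of genomic intervals
#'
#' Coordinates are kept 0-based half-open. Optional columns 4-6
#' (name, score, strand) are populated when present; missing optional fields
#' become `NA` (strand `"*"`).
#'
#' @param path Path to a tab-separated BED file.
#' @param chrom_sizes Optional chrom-sizes tibble (see [read_chrom_sizes()]);
#'   when supplied, intervals are validated against chromosome bounds.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, in file order.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3)) {
    stop("BED parse error at line ", which(n_col < 3)[1],
         ": fewer than 3 columns", call. = FALSE)
  }
  get_col <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("BED parse error at line ", bad[1], ": non-integer coordinates",
         call. = FALSE)
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    stop("BED parse error at line ", bad[1], ": start >= end or negative",
         call. = FALSE)
  }
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  out <- tibble::tibble(
    chrom = get_col(1),
    start = start,
    end = end,
    name = get_col(4),
    score = suppressWarnings(as.numeric(get_col(5))),
    strand = strand
  )
  if (!is.null(chrom_sizes)) check_bounds(out, chrom_sizes, "BED intervals")
  out
}

#' Write intervals to a sorted BED file
#'
#' Output is coordinate-sorted and tab-separated. Missing names and strands
#' are written as `"."`, missing scores as `0`.
#'
#' @param x An interval tibble (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end)
  if (any(c("name", "score", "strand") %in% names(x))) {
    nm <- if ("name" %in% names(x)) x$name else NA_character_
    sc <- if ("score" %in% names(x)) x$score else NA_real_
    st <- if ("strand" %in% names(x)) x$strand else NA_character_
    out$name <- ifelse(is.na(nm), ".", nm)
    out$score <- ifelse(is.na(sc), 0, sc)
    st <- ifelse(is.na(st) | !st %in% c("+", "-"), ".", st)
    out$strand <- st
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(x)
}

rm_required_cols <- c("genoName", "genoStart", "genoEnd", "strand",
                      "repName", "repClass", "repFamily", "milliDiv")

#' Read a RepeatMasker track table (UCSC dialect)
#'
#' Expects a tab-separated table with a header naming at least the columns
#' `genoName`, `genoStart`, `genoEnd`, `strand`, `repName`, `repClass`,
#' `repFamily`, `milliDiv` (a leading `#` on the header is tolerated).
#' Rows of class `Low_complexity` or `Simple_repeat` are removed, matching
#' the standard practice of excluding non-TE repeats before any
#' peak-vs-repeat analysis. `milliDiv` is converted to percent divergence.
#'
#' @param path Path to the table.
#' @param drop_classes Repeat classes to exclude.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `family`
#'   (the repeat name, e.g. `"RSINE1"`), `class_name` (e.g. `"SINE"`),
#'   `group` (the RepeatMasker family grouping, e.g. `"B4"`), and
#'   `divergence_pct`.
#' @export
read_repeatmasker <- function(path,
                              drop_classes = c("Low_complexity",
                                               "Simple_repeat")) {
  header <- readLines(path, n = 1)
  header <- sub("^#", "", header)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  missing <- setdiff(rm_required_cols, cols)
  if (length(missing) > 0) {
    stop("RepeatMasker table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1,
                         col.names = cols, comment.char = "",
                         stringsAsFactors = FALSE)
  x <- x[!x$repClass %in% drop_classes, , drop = FALSE]
  tibble::tibble(
    chrom = as.character(x$genoName),
    start = as.integer(x$genoStart),
    end = as.integer(x$genoEnd),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*"),
    family = as.character(x$repName),
    class_name = as.character(x$repClass),
    group = as.character(x$repFamily),
    divergence_pct = as.numeric(x$milliDiv) / 10
  )
}

#' Write repeat annotations as a RepeatMasker-style track table
#'
#' @param x A repeat tibble as returned by [read_repeatmasker()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_repeatmasker <- function(x, path) {
  out <- data.frame(
    genoName = x$chrom,
    genoStart = x$start,
    genoEnd = x$end,
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "+"),
    repName = x$family,
    repClass = x$class_name,
    repFamily = if ("group" %in% names(x)) x$group else x$class_name,
    milliDiv = as.integer(round((x$divergence_pct %||% 0) * 10))
  )
  out <- out[order(out$genoName, out$genoStart), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(x)
}

#' Classify peaks as repeat-associated (RABS) or not
#'
#' A peak is labelled `RABS` when a single repeat covers at least
#' `min_fraction` of the peak's length; the best-covering repeat (maximal
#' overlap, ties broken by leftmost repeat start) is reported. Peaks below
#' the threshold are labelled `Non-RABS` and keep the best overlap fraction
#' (possibly 0) with the repeat fields set to `NA`.
#'
#' @param peaks Interval tibble of ChIP-seq peaks.
#' @param repeats Repeat tibble (see [read_repeatmasker()]).
#' @param min_fraction Minimum fraction of the peak covered by one repeat,
#'   in (0, 1]. Default 0.5, the conventional 50% criterion.
#' @return A tibble with one row per peak, in input order: the peak columns,
#'   `repeat_family`, `repeat_class`, `repeat_start`, `repeat_end`,
#'   `repeat_divergence`, `overlap_bp`, `fraction_of_peak`, `label`.
#' @export
classify_rabs <- function(peaks, repeats, min_fraction = 0.5) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be a single number in (0, 1]", call. = FALSE)
  }
  base <- tibble::tibble(
    chrom = peaks$chrom %||% character(),
    start = peaks$start %||% integer(),
    end = peaks$end %||% integer(),
    peak_name = if ("name" %in% names(peaks)) peaks$name else NA_character_,
    repeat_family = NA_character_,
    repeat_class = NA_character_,
    repeat_start = NA_integer_,
    repeat_end = NA_integer_,
    repeat_divergence = NA_real_,
    overlap_bp = 0L,
    fraction_of_peak = 0,
    label = "Non-RABS"
  )
  if (nrow(base) == 0) return(base)
  check_intervals(peaks, "peaks")
  if (nrow(repeats) > 0) {
    check_intervals(repeats, "repeats")
    pg <- tbl_to_gr(peaks)
    rg <- tbl_to_gr(repeats)
    ov <- GenomicRanges::findOverlaps(pg, rg, ignore.strand = TRUE)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      ov_bp <- pmin(peaks$end[qh], repeats$end[sh]) -
        pmax(peaks$start[qh], repeats$start[sh])
      # best repeat per peak: max overlap, tie -> leftmost repeat start
      ord <- order(qh, -ov_bp, repeats$start[sh])
      keep <- !duplicated(qh[ord])
      qb <- qh[ord][keep]
      sb <- sh[ord][keep]
      ob <- ov_bp[ord][keep]
      frac <- ob / (peaks$end[qb] - peaks$start[qb])
      base$overlap_bp[qb] <- as.integer(ob)
      base$fraction_of_peak[qb] <- frac
      is_rabs <- frac >= min_fraction
      hit <- qb[is_rabs]
      rep_idx <- sb[is_rabs]
      base$label[hit] <- "RABS"
      base$repeat_family[hit] <- repeats$family[rep_idx]
      base$repeat_class[hit] <- if ("class_name" %in% names(repeats)) {
        repeats$class_name[rep_idx]
      } else {
        NA_character_
      }
      base$repeat_start[hit] <- repeats$start[rep_idx]
      base$repeat_end[hit] <- repeats$end[rep_idx]
      base$repeat_divergence[hit] <- if ("divergence_pct" %in% names(repeats)) {
        repeats$divergence_pct[rep_idx]
      } else {
        NA_real_
      }
    }
  }
  base
}

#' Distance from each query interval to its nearest subject interval
#'
#' Distances are edge gaps in bp: overlapping or book-ended (immediately
#' adjacent) intervals have distance 0. Strand is ignored. Queries on
#' chromosomes carrying no subject report `NA`.
#'
#' @param queries,subjects Interval tibbles.
#' @return A tibble with one row per query: the query columns plus
#'   `subject_chrom`, `subject_start`, `subject_end`, `distance`.
#' @export
nearest_distance <- function(queries, subjects) {
  check_intervals(queries, "queries")
  if (nrow(subjects) == 0) stop("subjects must be non-empty", call. = FALSE)
  check_intervals(subjects, "subjects")
  qg <- tbl_to_gr(queries)
  sg <- tbl_to_gr(subjects)
  # unify seqlevels so distanceToNearest sees a common namespace
  lv <- union(as.character(GenomeInfoDb::seqlevels(qg)),
              as.character(GenomeInfoDb::seqlevels(sg)))
  GenomeInfoDb::seqlevels(qg) <- lv
  GenomeInfoDb::seqlevels(sg) <- lv
  hits <- GenomicRanges::distanceToNearest(qg, sg, ignore.strand = TRUE)
  out <- tibble::tibble(
    chrom = queries$chrom,
    start = queries$start,
    end = queries$end,
    subject_chrom = NA_character_,
    subject_start = NA_integer_,
    subject_end = NA_integer_,
    distance = NA_real_
  )
  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    out$subject_chrom[qh] <- subjects$chrom[sh]
    out$subject_start[qh] <- subjects$start[sh]
    out$subject_end[qh] <- subjects$end[sh]
    out$distance[qh] <- as.numeric(S4Vectors::mcols(hits)$distance)
  }
  out
}

#' Draw a random repeat set matching the familial composition of RABS calls
#'
#' Samples, uniformly without replacement within each family, as many
#' genome-wide repeat copies as there are RABS calls of that family —
#' the standard control set for comparing signal at bound vs unbound copies.
#'
#' @param calls Output of [classify_rabs()].
#' @param all_repeats Genome-wide repeat tibble to sample from.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A repeat tibble with exactly the RABS per-family copy counts.
#' @export
matched_random_repeats <- function(calls, all_repeats, seed = 1L) {
  rabs <- calls[calls$label == "RABS", , drop = FALSE]
  comp <- table(rabs$repeat_family)
  with_seed(seed, {
    picked <- lapply(names(comp), function(fam) {
      idx <- which(all_repeats$family == fam)
      need <- as.integer(comp[[fam]])
      if (length(idx) < need) {
        stop("family ", fam, ": need ", need, " copies but only ",
             length(idx), " available", call. = FALSE)
      }
      idx[sample.int(length(idx), need)]
    })
    dplyr::slice(all_repeats, sort(unlist(picked)))
  })
}
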