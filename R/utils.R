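# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seed for replicate k of a master seed; stays within
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 65537) %% 2147483647L)
}

# Convert a 0-based half-open interval tibble to GRanges (1-based closed).
tbl_to_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[is.na(s) | !s %in% c("+", "-")] <- "*"
    s
  } else {
    "*"
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

interval_cols <- c("chrom", "start", "end")

check_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) {
    stop(what, " must be a data frame", call. = FALSE)
  }
  missing <- setdiff(interval_cols, names(x))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop(what, ": invalid interval (need 0 <= start < end) at row ", bad[1],
         call. = FALSE)
  }
  invisible(x)
}

check_bounds <- function(x, chrom_sizes, what = "intervals") {
  sizes <- chrom_sizes_lookup(chrom_sizes)
  unknown <- setdiff(unique(x$chrom), names(sizes))
  if (length(unknown) > 0) {
    stop(what, ": chromosome(s) not in chrom sizes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  over <- which(x$end > unname(sizes[x$chrom]))
  if (length(over) > 0) {
    stop(what, ": interval exceeds chromosome length at row ", over[1],
         call. = FALSE)
  }
  invisible(x)
}

chrom_sizes_lookup <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stats::setNames(as.numeric(chrom_sizes$length), chrom_sizes$chrom)
  } else {
    chrom_sizes
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
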