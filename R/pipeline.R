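# End-to-end orchestration: simulate (or ingest) -> classify RABS ->
# enrichment -> motif analyses -> maturation/divergence -> report.

#' RABS fraction summary across peak sets
#'
#' For each named peak set: total peaks, the RABS count and fraction, and
#' the focal family's share of RABS (with a zero-denominator flag when a
#' set has no RABS at all).
#'
#' @param peak_sets Named list of peak interval tibbles.
#' @param repeats Repeat tibble.
#' @param focal_family Family name whose share of RABS is reported.
#' @param min_fraction RABS threshold (default 0.5).
#' @return A tibble: `set`, `n_peaks`, `n_rabs`, `rabs_fraction`,
#'   `n_focal`, `focal_fraction_of_rabs`, `no_rabs`.
#' @export
rabs_fraction_summary <- function(peak_sets, repeats, focal_family,
                                  min_fraction = 0.5) {
  if (length(peak_sets) == 0) stop("need at least one peak set",
                                   call. = FALSE)
  if (is.null(names(peak_sets))) {
    names(peak_sets) <- paste0("set", seq_along(peak_sets))
  }
  dplyr::bind_rows(lapply(names(peak_sets), function(nm) {
    calls <- classify_rabs(peak_sets[[nm]], repeats,
                           min_fraction = min_fraction)
    n <- nrow(calls)
    n_rabs <- sum(calls$label == "RABS")
    n_focal <- sum(calls$label == "RABS" &
                     calls$repeat_family == focal_family, na.rm = TRUE)
    tibble::tibble(
      set = nm, n_peaks = n, n_rabs = n_rabs,
      rabs_fraction = if (n > 0) n_rabs / n else 0,
      n_focal = n_focal,
      focal_fraction_of_rabs = if (n_rabs > 0) n_focal / n_rabs else 0,
      no_rabs = n_rabs == 0
    )
  }))
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Simulates a dataset under `sim_config` (or accepts a pre-built
#' [simulate_dataset()] object), classifies peaks into RABS/Non-RABS,
#' quantifies per-family enrichment against the constrained-shuffle null,
#' runs the motif analyses (discriminative k-mers, density profile, optimal
#' E-Box spacing), the maturation and K2P-divergence summaries, and the
#' sister-lineage motif-gain comparison. Intermediate tables are written to
#' `out_dir` when given; reruns with identical configuration reproduce the
#' report.
#'
#' @param sim_config A [simulation_config()], or a `rabs_simulation`.
#' @param out_dir Optional output directory for artifacts.
#' @param n_replicates Bootstrap replicates for the enrichment null.
#' @param min_fraction RABS overlap threshold.
#' @param k Discriminative k-mer length.
#' @param flank Density-profile half-window (bp).
#' @return A list of class `rabs_report`.
#' @export
run_pipeline <- function(sim_config, out_dir = NULL, n_replicates = 100L,
                         min_fraction = 0.5, k = 6L, flank = 100L) {
  sim <- if (inherits(sim_config, "rabs_simulation")) {
    sim_config
  } else if (inherits(sim_config, "simulation_config")) {
    simulate_dataset(sim_config,
                     out_dir = if (is.null(out_dir)) NULL
                     else file.path(out_dir, "data"))
  } else {
    stop("sim_config must be a simulation_config or rabs_simulation",
         call. = FALSE)
  }
  config <- sim$config
  seed <- config$seed

  # --- RABS classification ------------------------------------------------
  calls <- classify_rabs(sim$peaks, sim$te_annotations,
                         min_fraction = min_fraction)
  fractions <- rabs_fraction_summary(list(peaks = sim$peaks),
                                     sim$te_annotations,
                                     focal_family = config$te_family,
                                     min_fraction = min_fraction)

  # --- enrichment ---------------------------------------------------------
  enr <- enrichment_report(sim$peaks, sim$te_annotations, sim$tss,
                           sim$chrom_sizes, n_replicates = n_replicates,
                           min_fraction = min_fraction,
                           seed = child_seed(seed, 11L))

  # --- motif analyses -----------------------------------------------------
  truth <- sim$truth
  bound_seqs <- sim$copies$seq[truth$bound]
  unbound_seqs <- sim$copies$seq[!truth$bound]
  kmers <- if (length(bound_seqs) > 0 && length(unbound_seqs) > 0) {
    kmer_enrichment(bound_seqs, unbound_seqs, k = k)
  } else {
    NULL
  }
  focal_ann <- sim$te_annotations[
    sim$te_annotations$family == config$te_family, , drop = FALSE]
  motif_hits <- dplyr::bind_rows(lapply(
    c("E-Box", "RORE", "D-Box"),
    function(m) scan_iupac(sim$genome, m)
  ))
  merged <- merge_hits(motif_hits)
  profile <- density_profile(focal_ann, merged, flank = flank,
                             chrom_sizes = sim$chrom_sizes)
  ebox_hits <- scan_iupac(stats::setNames(sim$copies$seq,
                                          sim$copies$copy_id),
                          "E-Box optimal")
  spacing <- nearest_motif_spacing(ebox_hits)

  # --- maturation and divergence ------------------------------------------
  mat_cols <- grep("^matured_", names(truth), value = TRUE)
  maturation_summary <- tibble::tibble(
    motif = sub("^matured_", "", mat_cols),
    matured_fraction = vapply(mat_cols, function(cc) mean(truth[[cc]]),
                              numeric(1))
  )
  cons <- config$consensus$sequence
  k2p <- dplyr::bind_rows(lapply(sim$copies$seq, function(s) {
    k2p_divergence(cons, s)
  }))
  k2p$copy_id <- sim$copies$copy_id

  # --- lineage split -------------------------------------------------------
  split <- simulate_lineage_split(sim$copies, config)
  flags_mouse <- maturation_flags(split$mouse$seq, config$consensus)
  pair_mouse <- rowSums(flags_mouse[, config$designated_pair,
                                    drop = FALSE]) ==
    length(config$designated_pair)
  orth <- split$ortholog_map$copy_id[split$ortholog_map$orthologous]
  mouse_orth <- split$mouse[split$mouse$copy_id %in% orth, ]
  rat_orth <- split$rat[split$rat$copy_id %in% orth, ]
  bound_ids <- mouse_orth$copy_id[
    pair_mouse[match(mouse_orth$copy_id, split$mouse$copy_id)]]
  gain <- NULL
  if (length(bound_ids) > 0 && length(bound_ids) < length(orth)) {
    gain <- dplyr::bind_rows(
      mouse = motif_gain_fold_change(
        mouse_orth$seq[mouse_orth$copy_id %in% bound_ids],
        mouse_orth$seq[!mouse_orth$copy_id %in% bound_ids],
        "E-Box optimal"),
      rat = motif_gain_fold_change(
        rat_orth$seq[rat_orth$copy_id %in% bound_ids],
        rat_orth$seq[!rat_orth$copy_id %in% bound_ids],
        "E-Box optimal"),
      .id = "lineage"
    )
  }

  report <- structure(list(
    fractions = fractions,
    calls = calls,
    enrichment = enr,
    kmer_enrichment = kmers,
    density_profile = profile,
    ebox_spacing = spacing,
    maturation_summary = maturation_summary,
    k2p = k2p,
    motif_gain = gain,
    truth = truth,
    provenance = list(seed = seed, n_replicates = n_replicates,
                      min_fraction = min_fraction, k = k, flank = flank,
                      n_peaks = nrow(sim$peaks),
                      n_copies = nrow(sim$copies))
  ), class = "rabs_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wr(calls, "rabs_calls.tsv")
    wr(fractions, "rabs_fractions.tsv")
    wr(as.data.frame(enr), "enrichment.tsv")
    if (!is.null(kmers)) wr(utils::head(kmers, 100), "kmer_enrichment.tsv")
    wr(as.data.frame(profile), "density_profile.tsv")
    wr(maturation_summary, "maturation_summary.tsv")
    wr(k2p, "k2p_divergence.tsv")
    if (!is.null(gain)) wr(gain, "motif_gain.tsv")
    jsonlite::write_json(
      list(provenance = report$provenance,
           rabs_fraction = fractions$rabs_fraction[1],
           top_family = enr$family[1],
           top_ratio = enr$ratio[1],
           spacing_mode = spacing_mode(spacing),
           mean_k2p = mean(k2p$d, na.rm = TRUE)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' Modal value of a spacing distribution
#'
#' @param spacing Numeric vector of spacings (bp).
#' @return The most frequent value (smallest on ties), or `NA` if empty.
#' @export
spacing_mode <- function(spacing) {
  if (length(spacing) == 0) return(NA_real_)
  tab <- table(spacing)
  as.numeric(names(tab)[which.max(tab)])
}

#' @export
print.rabs_report <- function(x, ...) {
  cat("<rabs_report>\n")
  cat("  peaks:", x$provenance$n_peaks,
      "| copies:", x$provenance$n_copies, "\n")
  cat("  RABS fraction:", round(x$fractions$rabs_fraction[1], 3), "\n")
  cat("  top enriched family:", x$enrichment$family[1],
      sprintf("(ratio %.2f, p = %.3g)", x$enrichment$ratio[1],
              x$enrichment$p_value[1]), "\n")
  if (length(x$ebox_spacing) > 0) {
    cat("  optimal E-Box spacing mode:", spacing_mode(x$ebox_spacing),
        "bp\n")
  }
  cat("  mean K2P divergence:", round(mean(x$k2p$d, na.rm = TRUE), 4), "\n")
  invisible(x)
}
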