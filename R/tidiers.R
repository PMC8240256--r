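# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a family-enrichment result
#'
#' @param x An `rabs_enrichment` object from [enrichment_report()].
#' @param ... Unused.
#' @return A plain tibble of per-family rows.
#' @export
tidy.rabs_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a family-enrichment result
#'
#' @param x An `rabs_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble: number of families, peaks, replicates, the top
#'   family and its ratio and p-value, and how many families pass the
#'   copy-count filter at p < 0.05.
#' @export
glance.rabs_enrichment <- function(x, ...) {
  tibble::tibble(
    n_families = nrow(x),
    n_peaks = attr(x, "n_peaks"),
    n_replicates = attr(x, "n_replicates"),
    top_family = x$family[1],
    top_ratio = x$ratio[1],
    top_p_value = x$p_value[1],
    n_significant_filtered = sum(x$p_value < 0.05 & x$passes_count_filter)
  )
}

#' Plot observed copies against enrichment ratio per family
#'
#' The classic enrichment overview: each family at its observed bound-copy
#' count (x, log scale) and observed/expected ratio (y), with the
#' copy-count filter marked.
#'
#' @param object An `rabs_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rabs_enrichment <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$ratio) & df$observed > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$ratio)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_value < 0.05)) +
    ggplot2::geom_vline(xintercept = attr(object, "count_filter"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "observed bound copies",
                  y = "observed / expected",
                  colour = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' Plot a score-weighted motif density profile
#'
#' @param object An `rabs_density_profile` from [density_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rabs_density_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$value,
                               colour = .data$motif)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from region center (bp)",
                  y = "mean score-weighted motif density") +
    ggplot2::theme_minimal()
}

#' Histogram of nearest-motif spacings
#'
#' @param spacing Numeric vector from [nearest_motif_spacing()].
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot object.
#' @export
plot_spacing <- function(spacing, binwidth = 1) {
  ggplot2::ggplot(tibble::tibble(spacing = spacing),
                  ggplot2::aes(x = .data$spacing)) +
    ggplot2::geom_histogram(binwidth = binwidth) +
    ggplot2::labs(x = "start-to-start spacing to nearest motif (bp)",
                  y = "count") +
    ggplot2::theme_minimal()
}

#' Histogram of per-copy K2P divergence
#'
#' @param k2p A tibble with a `d` column (e.g. the `k2p` element of a
#'   [run_pipeline()] report).
#' @param binwidth Bin width in substitutions/site.
#' @return A ggplot object.
#' @export
plot_divergence <- function(k2p, binwidth = 0.005) {
  ggplot2::ggplot(k2p[!is.na(k2p$d), , drop = FALSE],
                  ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(binwidth = binwidth) +
    ggplot2::labs(x = "K2P divergence from consensus (subst./site)",
                  y = "copies") +
    ggplot2::theme_minimal()
}
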