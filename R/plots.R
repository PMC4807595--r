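#' Score distributions of scored candidate sites
#'
#' Faceted histograms of every score column present in a [score_sites()]
#' result.
#'
#' @param scored Scored site tibble.
#' @param bins Histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(scored, bins = 30) {
  score_cols <- intersect(c("annotation_score", "specificity_score", "doench",
                            "xu", "custom"), names(scored))
  if (length(score_cols) == 0) stop("no score columns found")
  long <- tidyr::pivot_longer(scored[, score_cols], dplyr::everything(),
                              names_to = "score", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::facet_wrap(~score, scales = "free") +
    ggplot2::labs(x = "score value", y = "designs") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of gene-level screen results
#'
#' Gene log2 fold change against -log10 p, with the p = 0.05 threshold
#' marked.
#'
#' @param object A `screen_gene_results` from [gene_test()].
#' @param alpha Threshold line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_gene_results <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "gene log2 fold change (control-centred)",
                  y = "-log10 Wilcoxon p") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-guide fold changes for selected genes
#'
#' Dot plot of centred log2 fold changes of each gene's guides, with the
#' gene median marked — the per-gene view used to judge what fraction of a
#' gene's guides moved with the phenotype.
#'
#' @param l2fc Per-guide table from [normalize_and_fold_change()].
#' @param gene_map Tibble with `design_id`, `gene_id`.
#' @param genes Character vector of genes to show.
#' @return A ggplot object.
#' @export
plot_gene_foldchanges <- function(l2fc, gene_map, genes) {
  df <- dplyr::inner_join(l2fc, gene_map, by = "design_id") |>
    dplyr::filter(.data$gene_id %in% genes)
  if (nrow(df) == 0) stop("no guides found for the requested genes")
  med <- df |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(m = stats::median(.data$centred_l2fc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id,
                                   y = .data$centred_l2fc)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::geom_point(data = med,
                        ggplot2::aes(x = .data$gene_id, y = .data$m),
                        colour = "red", shape = 95, size = 10) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "centred log2 fold change") +
    ggplot2::theme_minimal()
}
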