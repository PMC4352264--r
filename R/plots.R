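# Thin ggplot2 layers over the result tibbles; all numbers shown are taken
# from the tibbles unchanged.

#' Bar chart of motif-pattern counts
#'
#' @param tally A `motif_tally` from [tally_motifs()].
#' @return A ggplot.
#' @export
plot_motif_tally <- function(tally) {
  stopifnot(inherits(tally, "motif_tally"))
  ggplot2::ggplot(tally$per_pattern,
                  ggplot2::aes(x = stats::reorder(.data$pattern, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "motifs",
                  title = sprintf("%d CCCH motifs in %d proteins",
                                  tally$totals$n_motifs,
                                  tally$totals$n_motif_proteins)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sequence-logo style information-content profile
#'
#' @param profile Output of [position_profile()].
#' @return A ggplot of per-position information content with residue fills
#'   stacked by contribution (`freq * ic`).
#' @export
plot_position_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data$freq * .data$ic,
                               fill = .data$residue)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "motif position", y = "bits") +
    ggplot2::theme_minimal()
}

#' Clustered expression heatmap
#'
#' @param x A `clustered_heatmap` from [cluster_atlas()].
#' @return A ggplot tile map with both axes in dendrogram order.
#' @method autoplot clustered_heatmap
#' @export
autoplot.clustered_heatmap <- function(x, ...) {
  long <- tidyr::pivot_longer(x$values, -"gene_id",
                              names_to = "sample", values_to = "log2fc")
  long$gene_id <- factor(long$gene_id, levels = x$genes$order)
  long$sample <- factor(long$sample, levels = x$samples$order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                     fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Promoter cis-element map
#'
#' Sense-strand hits above each promoter's line, antisense below, mirroring
#' the usual -2 kb promoter diagrams.
#'
#' @param hits Hit tibble from [scan_promoter()].
#' @param promoter_length Window length for the x axis (default 2000).
#' @return A ggplot.
#' @export
plot_element_map <- function(hits, promoter_length = 2000) {
  hits <- mutate(hits, y = ifelse(.data$strand == "sense", 0.25, -0.25))
  ggplot2::ggplot(hits) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$start - promoter_length - 1,
                                     y = .data$y, colour = .data$motif,
                                     shape = .data$strand), size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$promoter_id)) +
    ggplot2::scale_y_continuous(limits = c(-1, 1), breaks = NULL) +
    ggplot2::labs(x = "position relative to translation start (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' qPCR fold-change panel
#'
#' @param folds Tibble from [ddct_fold()] (possibly several targets bound
#'   together).
#' @param cutoff Reference line for the induction cut-off (default 2).
#' @return A ggplot of log2 fold changes by timepoint, faceted by gene and
#'   treatment, significant points marked.
#' @export
plot_qpcr_folds <- function(folds, cutoff = 2) {
  ggplot2::ggplot(folds, ggplot2::aes(x = factor(.data$timepoint),
                                      y = log2(.data$fold))) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_point(data = filter(folds, .data$significant),
                        ggplot2::aes(y = log2(.data$fold) + 0.3),
                        shape = 8, size = 2) +
    ggplot2::geom_hline(yintercept = c(-log2(cutoff), log2(cutoff)),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$gene),
                        cols = ggplot2::vars(.data$treatment)) +
    ggplot2::labs(x = "hours of treatment", y = "log2 fold change vs 0 h") +
    ggplot2::theme_minimal()
}
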