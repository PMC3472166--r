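# ggplot2 views of the result objects: DEG count bars, isoform switch
# crossing plots, sample correlation heatmap, expression distribution.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_tile geom_histogram facet_grid facet_wrap labs scale_fill_gradient2
#'   scale_x_log10 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Bar chart of DEG counts per tissue and direction
#'
#' @param object A `deg_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.deg_result <- function(object, ...) {
  object$degs %>%
    count(.data$tissue, .data$direction) %>%
    ggplot(aes(x = .data$tissue, y = .data$n, fill = .data$direction)) +
    geom_col(position = "dodge") +
    labs(
      x = NULL, y = "differentially expressed features",
      fill = "direction",
      title = sprintf(
        ">%g-fold change in >=%d animals",
        object$params$fold_threshold, object$params$min_horses
      )
    ) +
    theme_minimal()
}

#' Per-animal crossing plots of isoform switch events
#'
#' One panel per animal and event, FPKM of the two isoforms before and
#' after exercise; a switch shows as crossing lines.
#'
#' @param object A `switch_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.switch_result <- function(object, ...) {
  if (nrow(object$profiles) == 0) {
    abort("no switch events to plot")
  }
  object$profiles %>%
    mutate(event = paste(.data$gene_id, .data$tissue)) %>%
    ggplot(aes(
      x = .data$timepoint, y = .data$fpkm,
      colour = .data$transcript_id, group = .data$transcript_id
    )) +
    geom_line() +
    geom_point() +
    facet_grid(
      rows = ggplot2::vars(.data$event), cols = ggplot2::vars(.data$horse),
      scales = "free_y"
    ) +
    labs(x = NULL, y = "FPKM", colour = "isoform") +
    theme_minimal()
}

#' Heatmap of the sample-sample correlation matrix
#'
#' @param corr Output of [sample_correlation()].
#' @return A ggplot object.
#' @export
plot_sample_correlation <- function(corr) {
  corr %>%
    pivot_longer(-"sample_id", names_to = "sample_b", values_to = "r") %>%
    ggplot(aes(x = .data$sample_id, y = .data$sample_b, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1), midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Histogram of per-feature mean FPKM
#'
#' @param fpkm Long FPKM tibble.
#' @param bins Number of bins.
#' @return A ggplot object (log10 x scale; zero means dropped).
#' @export
plot_fpkm_distribution <- function(fpkm, bins = 40) {
  fpkm %>%
    group_by(.data$feature_id) %>%
    summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop") %>%
    filter(.data$mean_fpkm > 0) %>%
    ggplot(aes(x = .data$mean_fpkm)) +
    geom_histogram(bins = bins) +
    scale_x_log10() +
    labs(x = "mean FPKM (log scale)", y = "features") +
    theme_minimal()
}
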