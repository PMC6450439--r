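#' Heatmap of per-sample pathway Z-scores
#'
#' @param pathway_z Tibble `set`, `sample_id`, `z`.
#' @return A ggplot.
#' @export
plot_pathway_heatmap <- function(pathway_z) {
  ggplot2::ggplot(pathway_z,
                  ggplot2::aes(x = .data$sample_id, y = .data$set,
                               fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "pathway Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Volcano plot of one contrast's DE results
#'
#' @param de A `de_result` tibble (one contrast).
#' @return A ggplot.
#' @export
plot_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2_ratio,
                                   y = -log10(pmax(.data$q, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 ratio vs matched vehicle", y = "-log10 q") +
    ggplot2::theme_minimal()
}

#' PCA scatter with per-group confidence ellipses
#'
#' @param pca Result of [pca_summary()].
#' @param n_ellipse Points used to draw each ellipse outline.
#' @return A ggplot.
#' @export
plot_pca <- function(pca, n_ellipse = 120) {
  coords <- pca$coordinates
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                            colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$variance_explained[2])) +
    ggplot2::theme_minimal()
  if (!is.null(pca$ellipses)) {
    ell <- pca$ellipses |> filter(!is.na(.data$semi_major))
    if (nrow(ell) > 0) {
      theta <- seq(0, 2 * pi, length.out = n_ellipse)
      outlines <- purrr::pmap_dfr(ell, function(group, center_x, center_y,
                                                semi_major, semi_minor,
                                                angle) {
        xx <- semi_major * cos(theta)
        yy <- semi_minor * sin(theta)
        tibble(group = group,
               PC1 = center_x + xx * cos(angle) - yy * sin(angle),
               PC2 = center_y + xx * sin(angle) + yy * cos(angle))
      })
      p <- p + ggplot2::geom_path(data = outlines, linetype = "dashed")
    }
  }
  p
}

#' Box plots of cell-type scores by group
#'
#' One panel per cell type (scores are never compared across types).
#'
#' @param scores Tibble from [cell_scores()].
#' @param samples Sample metadata (joined on `sample_id`).
#' @param group Metadata column used for the x axis.
#' @return A ggplot.
#' @export
plot_cell_scores <- function(scores, samples, group = "treatment") {
  df <- scores |> left_join(samples, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[group]], y = .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(y = "log2 cell-type score", x = NULL) +
    ggplot2::theme_minimal()
}
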