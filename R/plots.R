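#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_text
#'   labs theme_bw scale_color_manual facet_wrap
NULL

#' @export
ggplot2::autoplot

#' PCA score plot colored by disease group
#'
#' @param object A `crosstalk_pca` from [pca_qc()].
#' @param ... Unused.
#' @return A ggplot: PC1 vs PC2 sample scores, HC vs OA.
#' @export
autoplot.crosstalk_pca <- function(object, ...) {
  evr <- object$explained_variance_ratio
  ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2,
                            color = .data$group)) +
    geom_point(alpha = 0.8) +
    scale_color_manual(values = c(HC = "#4477AA", OA = "#CC3311")) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * evr[1]),
      y = if (length(evr) >= 2) sprintf("PC2 (%.1f%%)", 100 * evr[2]) else "PC2",
      color = "Group"
    ) +
    theme_bw()
}

#' Volcano plot of a differential-expression table
#'
#' Points at (log2 fold change, -log10 p); genes below `alpha` are colored by
#' direction and the top genes (per [volcano_annotations()]) are labeled.
#'
#' @param de_table Output of [differential_expression()].
#' @param top_n Number of genes to label (half per direction).
#' @param alpha Significance threshold used for coloring.
#' @return A ggplot.
#' @export
plot_volcano <- function(de_table, top_n = 20, alpha = 0.05) {
  v <- volcano_annotations(de_table, top_n = top_n) |>
    mutate(status = dplyr::case_when(
      .data$p_value < alpha & .data$direction == "up" ~ "up",
      .data$p_value < alpha & .data$direction == "down" ~ "down",
      TRUE ~ "ns"
    ))
  ggplot(v, aes(x = .data$log2fc, y = .data$neg_log10_p,
                color = .data$status)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_text(data = filter(v, .data$label), aes(label = .data$gene),
              size = 2.5, vjust = -0.6, show.legend = FALSE) +
    scale_color_manual(values = c(up = "#CC3311", down = "#4477AA",
                                  ns = "grey70")) +
    labs(x = "log2 fold change (OA - HC)", y = "-log10 p-value",
         color = NULL) +
    theme_bw()
}

#' Dot plot of over-representation results
#'
#' The conventional GO dot plot: top terms per category by adjusted p, gene
#' ratio on the x axis, point size the hit count, color the adjusted p-value.
#'
#' @param result Output of [enrich_ora()].
#' @param top_n Terms shown per category.
#' @return A ggplot.
#' @export
plot_enrichment <- function(result, top_n = 10) {
  top <- result |>
    group_by(.data$category) |>
    arrange(.data$adj_p, .data$p_value) |>
    slice(seq_len(min(top_n, n()))) |>
    ungroup() |>
    mutate(term = stats::reorder(.data$term_id, -.data$p_value))
  ggplot(top, aes(x = .data$gene_ratio, y = .data$term,
                  size = .data$k, color = .data$adj_p)) +
    geom_point() +
    facet_wrap(~category, scales = "free_y") +
    labs(x = "Gene ratio", y = NULL, size = "Hits", color = "adj. p") +
    theme_bw()
}

#' Bar chart of communication-map edge counts by direction class
#'
#' @param map Output of [build_communication_map()].
#' @return A ggplot with one bar per direction class (BL->BL, BL->SY,
#'   SY->BL, SY->SY).
#' @export
plot_map_summary <- function(map) {
  classes <- summarize_map(map)$classes
  ggplot(classes, aes(x = .data$direction_class, y = .data$n_edges)) +
    geom_col(fill = "#4477AA") +
    labs(x = "Direction class (source tissue -> target tissue)",
         y = "Ligand-receptor edges") +
    theme_bw()
}
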