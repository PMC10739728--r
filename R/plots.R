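#' @import ggplot2
NULL

#' Plot a clustered embedding
#'
#' UMAP scatter colored by cluster label.
#'
#' @param embedding an [sc_embedding] with UMAP coordinates.
#' @param color_by optional per-cell vector overriding the cluster color.
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, color_by = NULL) {
  df <- tidy(embedding)
  df$color <- if (is.null(color_by)) factor(df$cluster) else color_by
  ggplot(df, aes(.data$UMAP1, .data$UMAP2, color = .data$color)) +
    geom_point(size = 0.8) +
    labs(color = if (is.null(color_by)) "cluster" else NULL) +
    theme_minimal()
}

#' Plot query cells projected onto the reference embedding
#'
#' Reference cells in grey, projected query coordinates colored by query
#' group.
#'
#' @param embedding the reference [sc_embedding].
#' @param projection a `projection_result` from [project_cells()].
#' @param group_by optional per-query-cell grouping for the color.
#' @return A ggplot.
#' @export
plot_projection <- function(embedding, projection, group_by = NULL) {
  ref <- tidy(embedding)
  qry <- projection[projection$mappable, ]
  grp <- if (is.null(group_by)) "query" else group_by[projection$mappable]
  ggplot() +
    geom_point(data = ref, aes(.data$UMAP1, .data$UMAP2),
               color = "grey80", size = 0.8) +
    geom_point(data = tibble(x = qry$proj_x, y = qry$proj_y, group = grp),
               aes(.data$x, .data$y, color = .data$group), size = 0.9) +
    labs(x = "UMAP1", y = "UMAP2", color = NULL) +
    theme_minimal()
}

#' Bar plot of mapping ratios
#'
#' @param ratios tibble from [mapping_ratio()].
#' @return A ggplot.
#' @export
plot_mapping_ratio <- function(ratios) {
  ggplot(ratios, aes(factor(.data$ref_label), .data$ratio,
                     fill = factor(.data$ref_label))) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~group) +
    labs(x = "reference subpopulation", y = "fraction of mapped cells") +
    theme_minimal()
}

#' Heatmap of pairwise clonotype overlap
#'
#' @param overlap the `pairs` tibble from [clonotype_overlap()].
#' @param value `"jaccard"` or `"shared"`.
#' @return A ggplot.
#' @export
plot_overlap <- function(overlap, value = c("jaccard", "shared")) {
  value <- match.arg(value)
  ggplot(overlap, aes(.data$group_a, .data$group_b,
                      fill = .data[[value]])) +
    geom_tile() +
    geom_text(aes(label = signif(.data[[value]], 3)), size = 3) +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = value) +
    theme_minimal()
}

#' CDR3beta length spectratype bar plot
#'
#' @param spectra result of [cdr3_spectratype()].
#' @return A ggplot.
#' @export
plot_spectratype <- function(spectra) {
  ggplot(spectra$lengths, aes(.data$length, .data$fraction)) +
    geom_col(fill = "steelblue") +
    geom_vline(xintercept = spectra$modal_length, linetype = "dashed") +
    labs(x = "CDR3β length (aa)", y = "fraction of cells") +
    theme_minimal()
}

#' Lineage tree over the embedding
#'
#' Cells in grey, centroids and MST edges overlaid.
#'
#' @param embedding the [sc_embedding] the graph was built from.
#' @param graph a `lineage_graph`.
#' @return A ggplot.
#' @export
plot_lineage <- function(embedding, graph) {
  cells <- tidy(embedding)
  cent <- graph$centroids
  names(cent)[2:3] <- c("x", "y")
  seg <- dplyr::left_join(graph$edges,
                          dplyr::rename(cent, xa = "x", ya = "y"),
                          by = c("from" = "cluster")) |>
    dplyr::left_join(dplyr::rename(cent, xb = "x", yb = "y"),
                     by = c("to" = "cluster"))
  ggplot() +
    geom_point(data = cells, aes(.data$UMAP1, .data$UMAP2),
               color = "grey85", size = 0.7) +
    geom_segment(data = seg, aes(x = .data$xa, y = .data$ya,
                                 xend = .data$xb, yend = .data$yb)) +
    geom_label(data = cent, aes(.data$x, .data$y,
                                label = .data$cluster), size = 3) +
    labs(x = "UMAP1", y = "UMAP2") +
    theme_minimal()
}
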