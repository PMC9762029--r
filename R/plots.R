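# ggplot2 displays for the main result types.

#' Marker dot plot
#'
#' The classic cluster-by-marker display: dot size is the fraction of the
#' cluster's cells expressing the gene, color its mean log-normalized
#' expression.
#'
#' @param object An `sc_annotation` from [annotate_clusters()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sc_annotation <- function(object, ...) {
  ggplot2::ggplot(object$dotplot,
                  ggplot2::aes(x = factor(.data$cluster_id),
                               y = .data$gene_id,
                               size = .data$frac_expressing,
                               color = .data$mean_expr)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 6, limits = c(0, 1)) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::facet_grid(cell_type ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "cluster", y = NULL, size = "fraction\nexpressing",
                  color = "mean\nexpression") +
    ggplot2::theme_minimal()
}

#' Cluster composition bars
#'
#' Per-sample cluster cell counts normalized to the composition scale.
#'
#' @param composition A tibble from [cluster_composition()].
#' @return A ggplot.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = factor(.data$cluster_id),
                               y = .data$n_normalized,
                               fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "cluster", y = "cells per 10,000", fill = "sample") +
    ggplot2::theme_minimal()
}

#' Subgenome proportions of expressed genes
#'
#' Stacked per-cell-type proportions of expressed genes by subgenome.
#'
#' @param proportions A tibble from [subgenome_proportions()].
#' @return A ggplot.
#' @export
plot_subgenome_proportions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$cell_type, y = .data$proportion,
                               fill = .data$subgenome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of expressed genes",
                  fill = "subgenome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Dominance counts per cell type and subgenome
#'
#' @param counts A tibble from [dominance_counts()].
#' @return A ggplot.
#' @export
plot_dominance_counts <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$cell_type, y = .data$n,
                               fill = .data$subgenome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "predominantly expressed groups",
                  fill = "subgenome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Heat DEG counts per cell type
#'
#' Up/down DEG counts per cell type from a heat DEG table.
#'
#' @param heat_table A tibble from [heat_deg_table()].
#' @return A ggplot.
#' @export
plot_deg_counts <- function(heat_table) {
  counts <- dplyr::count(heat_table, .data$cell_type, .data$direction)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$cell_type, y = .data$n,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "DEGs", fill = "direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' DEG-subset partition sizes (UpSet-style bars)
#'
#' @param object An `sc_deg_partition` from [deg_partition()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sc_deg_partition <- function(object, ...) {
  sizes <- object$membership |>
    dplyr::count(.data$direction, .data$subset, .data$n_types) |>
    dplyr::arrange(dplyr::desc(.data$n))
  ggplot2::ggplot(sizes,
                  ggplot2::aes(x = stats::reorder(.data$subset, -.data$n),
                               y = .data$n, fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "cell-type subset", y = "genes", fill = "direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Per-cell UMI totals by cell type and condition
#'
#' Violin display of the per-cell UMI depth, mirroring the control-vs-heat
#' depth comparison.
#'
#' @param ds An [sc_dataset()] with raw counts and cell-type labels.
#' @return A ggplot.
#' @export
plot_umi_totals <- function(ds) {
  df <- tibble(
    cell_type = ds$cells$cell_type,
    condition = ds$cells$condition,
    total_umi = Matrix::colSums(ds$counts)
  )
  df <- dplyr::filter(df, !is.na(.data$cell_type))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$total_umi,
                                   fill = .data$condition)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "UMIs per cell", fill = "condition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
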