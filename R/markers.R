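# Cluster-enriched gene calling and novel cell-type marker identification.

#' Subset a dataset by cell metadata
#'
#' Tidy filtering verb: keeps the cells whose metadata rows satisfy the
#' `dplyr::filter()` conditions, subsetting every layer consistently.
#'
#' @param ds An [sc_dataset()].
#' @param ... Conditions on the cells table, e.g. `condition == "control"`.
#' @return The subsetted dataset.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1))
#' control <- filter_cells(sim$dataset, condition == "control")
filter_cells <- function(ds, ...) {
  stopifnot(inherits(ds, "sc_dataset"))
  cells <- dplyr::filter(ds$cells, ...)
  idx <- match(cells$barcode, colnames(ds$counts))
  ds$counts <- ds$counts[, idx, drop = FALSE]
  if (!is.null(ds$lognorm)) ds$lognorm <- ds$lognorm[, idx, drop = FALSE]
  ds$cells <- cells
  ds
}

#' Cluster-enriched genes
#'
#' For each cluster, tests every gene cluster-versus-all-other-cells with the
#' two-part [hurdle_test()], BH-adjusts within the cluster, and calls a gene
#' enriched when it is detected in at least `cluster_enriched_min_frac` (25%)
#' of the cluster's cells, its log2 fold change exceeds
#' `cluster_enriched_log2fc` (0.36, i.e. 1.28-fold, one-sided: higher in the
#' cluster) and its BH q is at most `cluster_enriched_q` (0.01).
#'
#' @param ds An [sc_dataset()] with a lognorm layer and cluster labels.
#' @param clusters Clusters to analyse (default: all with >= 3 cells; smaller
#'   clusters are skipped with a warning).
#' @return A tibble of calls: `cluster_id`, `gene_id`, `log2fc`, `p`, `q`,
#'   `pct_target`, `pct_rest`, `mean_expr_target`.
#' @export
cluster_enriched_genes <- function(ds, clusters = NULL) {
  X <- get_lognorm(ds, "cluster_enriched_genes")
  th <- ds$thresholds
  cl <- ds$cells$cluster_id
  all_clusters <- sort(unique(cl[!is.na(cl)]))
  if (is.null(clusters)) clusters <- all_clusters
  sizes <- table(cl)
  small <- clusters[sizes[as.character(clusters)] < 3]
  if (length(small)) {
    warning("skipping clusters with < 3 cells: ",
            paste(small, collapse = ", "), call. = FALSE)
    clusters <- setdiff(clusters, small)
  }
  purrr::map(clusters, function(k) {
    in_k <- !is.na(cl) & cl == k
    res <- de_test(ds, which(in_k), which(!in_k), adjust = TRUE)
    a <- row_group_stats(X, which(in_k))
    res$mean_expr_target <- as.numeric(a$sum / a$n)
    res |>
      dplyr::mutate(cluster_id = k) |>
      dplyr::filter(.data$pct_a >= th$cluster_enriched_min_frac,
                    .data$log2fc > th$cluster_enriched_log2fc,
                    .data$q <= th$cluster_enriched_q) |>
      dplyr::select(cluster_id = "cluster_id", gene_id = "gene_id",
                    log2fc = "log2fc", p = "p", q = "q",
                    pct_target = "pct_a", pct_rest = "pct_b",
                    mean_expr_target = "mean_expr_target")
  }) |> dplyr::bind_rows()
}

#' Novel cell-type marker genes
#'
#' Calls a gene a marker of a cell type when it is detected in at least
#' `marker_target_frac` (25%) of the type's cells, in fewer than
#' `marker_other_frac` (25%) of the cells of every other type (individually by
#' default; set `other_rule = "pooled"` to compare against the pooled rest),
#' its log2 fold change versus all other labeled cells exceeds `marker_log2fc`
#' (0.5), and its hurdle-test p is at most `marker_p` (0.01; raw p by
#' convention, set `use = "q"` for BH-adjusted calls instead).
#'
#' @param ds An [sc_dataset()] with a lognorm layer and `cell_type` labels
#'   (other than "unknown") on at least two types.
#' @param use Gate on raw `"p"` (default) or BH `"q"`.
#' @param other_rule `"each"` (default): the <25% rule applies to each other
#'   type individually; `"pooled"`: to the pooled rest.
#' @return A tibble of calls: `cell_type`, `gene_id`, `log2fc`, `p`, `q`,
#'   `pct_target`, `pct_rest`, `max_pct_other`, `mean_expr_target`.
#' @export
cell_type_markers <- function(ds, use = c("p", "q"),
                              other_rule = c("each", "pooled")) {
  use <- match.arg(use)
  other_rule <- match.arg(other_rule)
  X <- get_lognorm(ds, "cell_type_markers")
  th <- ds$thresholds
  ct <- ds$cells$cell_type
  labeled <- !is.na(ct) & ct != "unknown"
  types <- sort(unique(ct[labeled]))
  if (length(types) < 2) {
    stop("cell_type_markers needs >= 2 labeled cell types", call. = FALSE)
  }
  # detection fraction per gene per type, for the per-type exclusivity rule
  pct_by_type <- vapply(types, function(t) {
    idx <- which(labeled & ct == t)
    as.numeric(Matrix::rowSums(X[, idx, drop = FALSE] > 0) / length(idx))
  }, numeric(nrow(X)))
  colnames(pct_by_type) <- types

  purrr::map(types, function(t) {
    in_t <- labeled & ct == t
    rest <- labeled & ct != t
    res <- de_test(ds, which(in_t), which(rest), adjust = TRUE)
    a <- row_group_stats(X, which(in_t))
    res$mean_expr_target <- as.numeric(a$sum / a$n)
    others <- setdiff(types, t)
    res$max_pct_other <- if (other_rule == "each") {
      apply(pct_by_type[, others, drop = FALSE], 1, max)
    } else {
      res$pct_b
    }
    gate_p <- if (use == "p") res$p else res$q
    res |>
      dplyr::mutate(cell_type = t, gate_p = gate_p) |>
      dplyr::filter(.data$pct_a >= th$marker_target_frac,
                    .data$max_pct_other < th$marker_other_frac,
                    .data$log2fc > th$marker_log2fc,
                    .data$gate_p <= th$marker_p) |>
      dplyr::select(cell_type = "cell_type", gene_id = "gene_id",
                    log2fc = "log2fc", p = "p", q = "q",
                    pct_target = "pct_a", pct_rest = "pct_b",
                    max_pct_other = "max_pct_other",
                    mean_expr_target = "mean_expr_target")
  }) |> dplyr::bind_rows()
}

#' Top markers by expression
#'
#' Ranks marker calls by mean log-normalized expression in their target
#' population (descending, ties broken by gene id) and returns the first `n`
#' per target.
#'
#' @param calls A call tibble from [cluster_enriched_genes()] or
#'   [cell_type_markers()] (must carry `mean_expr_target`).
#' @param n Markers to keep per target.
#' @return The ranked sublist, same columns as `calls`.
#' @export
top_markers <- function(calls, n = 20) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  target_col <- intersect(c("cluster_id", "cell_type"), names(calls))[1]
  if (is.na(target_col)) {
    stop("calls must carry a cluster_id or cell_type column", call. = FALSE)
  }
  calls |>
    dplyr::group_by(.data[[target_col]]) |>
    dplyr::arrange(dplyr::desc(.data$mean_expr_target), .data$gene_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup()
}
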