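# QC filtering, log-normalization, cluster composition/correlation and
# marker-based cluster annotation.

#' Quality-control filtering of cells
#'
#' Keeps cells whose UMI total lies in `[qc_umi_min, qc_umi_max]` and whose
#' detected-gene count lies in `[qc_genes_min, qc_genes_max]` (bounds
#' inclusive: the removal rules are stated as strictly "greater than"/"lower
#' than", so equality survives). Operates on the raw counts layer; the removed
#' barcodes and their reasons are attached as the QC report, retrievable with
#' [qc_report()]. Filtering is idempotent.
#'
#' @param ds An [sc_dataset()] with raw counts.
#' @return The filtered `sc_dataset`, with a `qc_report` attribute.
#' @export
qc_filter_cells <- function(ds) {
  stopifnot(inherits(ds, "sc_dataset"))
  th <- ds$thresholds
  totals <- Matrix::colSums(ds$counts)
  n_genes <- Matrix::colSums(ds$counts > 0)
  reasons <- character(ncol(ds$counts))
  add <- function(reasons, flag, label) {
    ifelse(flag, ifelse(reasons == "", label, paste(reasons, label, sep = ",")),
           reasons)
  }
  reasons <- add(reasons, totals < th$qc_umi_min, "umi_low")
  reasons <- add(reasons, totals > th$qc_umi_max, "umi_high")
  reasons <- add(reasons, n_genes < th$qc_genes_min, "genes_low")
  reasons <- add(reasons, n_genes > th$qc_genes_max, "genes_high")
  keep <- reasons == ""
  report <- tibble(
    barcode = colnames(ds$counts),
    total_umi = as.numeric(totals),
    n_genes = as.integer(n_genes),
    kept = unname(keep),
    reason = unname(ifelse(keep, NA_character_, reasons))
  )
  out <- ds
  out$counts <- ds$counts[, keep, drop = FALSE]
  if (!is.null(out$lognorm)) out$lognorm <- out$lognorm[, keep, drop = FALSE]
  out$cells <- out$cells[match(colnames(out$counts), out$cells$barcode), ]
  attr(out, "qc_report") <- report
  out
}

#' @rdname qc_filter_cells
#' @export
qc_report <- function(ds) {
  attr(ds, "qc_report")
}

#' Log-normalize UMI counts
#'
#' The LogNormalize transform: each cell's counts are scaled to a fixed total
#' (default 10,000) and mapped through the natural log with a pseudocount of
#' one, `x = ln(1 + count * scale / total)`. Zeros map to zeros, so the layer
#' stays sparse. The raw layer is retained alongside.
#'
#' @param ds An [sc_dataset()] whose cells all have a positive UMI total.
#' @param scale Per-cell scaling target.
#' @return The dataset with a `lognorm` layer added.
#' @export
log_normalize <- function(ds, scale = ds$thresholds$lognorm_scale) {
  stopifnot(inherits(ds, "sc_dataset"))
  totals <- Matrix::colSums(ds$counts)
  if (any(totals == 0)) {
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(colnames(ds$counts)[totals == 0], 3),
               collapse = ", "), call. = FALSE)
  }
  X <- ds$counts
  per_entry_scale <- rep(scale / totals, diff(X@p))
  X@x <- log1p(X@x * per_entry_scale)
  ds$lognorm <- X
  ds
}

#' Cluster composition across samples with tissue-enrichment tests
#'
#' Counts cells per cluster and sample, normalizes each sample to a fixed
#' total (`composition_scale`, default 10,000 cells), and, when both tissues
#' are present, tests each cluster for shoot/leaf enrichment with a 2x2 Fisher
#' exact test of (in cluster vs not) by (shoot vs leaf) on the raw cell
#' counts, BH-adjusted across clusters.
#'
#' @param ds An [sc_dataset()] with `cluster_id` assigned.
#' @param enrich_q Significance cutoff on the BH q for the direction flag.
#' @return A tibble with one row per (cluster, sample): `cluster_id`,
#'   `sample_id`, `tissue`, `n_cells`, `n_normalized`, and per-cluster
#'   `odds_ratio` (sample odds ratio of the 2x2 table), `fisher_p`, `bh_q`,
#'   `enrichment` ("shoot", "leaf" or "none"). The test columns are `NA` when
#'   a single tissue is present.
#' @export
cluster_composition <- function(ds, enrich_q = 0.05) {
  stopifnot(inherits(ds, "sc_dataset"))
  cells <- dplyr::filter(ds$cells, !is.na(.data$cluster_id))
  if (nrow(cells) == 0) stop("no cells carry a cluster_id", call. = FALSE)
  scale <- ds$thresholds$composition_scale
  comp <- cells |>
    dplyr::count(.data$cluster_id, .data$sample_id, .data$tissue,
                 name = "n_cells") |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(c("sample_id", "tissue"))),
      cluster_id = sort(unique(cells$cluster_id)),
      fill = list(n_cells = 0L)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(n_normalized = .data$n_cells * scale / sum(.data$n_cells)) |>
    dplyr::ungroup()

  tissues <- unique(cells$tissue)
  if (length(tissues) >= 2) {
    n_shoot <- sum(cells$tissue == "shoot")
    n_leaf <- sum(cells$tissue == "leaf")
    stats_tbl <- comp |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::summarise(
        in_shoot = sum(.data$n_cells[.data$tissue == "shoot"]),
        in_leaf = sum(.data$n_cells[.data$tissue == "leaf"]),
        .groups = "drop") |>
      dplyr::mutate(
        odds_ratio = (.data$in_shoot * (n_leaf - .data$in_leaf)) /
          ((n_shoot - .data$in_shoot) * .data$in_leaf),
        fisher_p = purrr::map2_dbl(.data$in_shoot, .data$in_leaf,
                                   function(s, l) {
          stats::fisher.test(matrix(c(s, n_shoot - s, l, n_leaf - l),
                                    nrow = 2))$p.value
        })) |>
      dplyr::mutate(
        bh_q = bh_adjust(.data$fisher_p),
        enrichment = dplyr::case_when(
          .data$bh_q <= enrich_q & .data$odds_ratio > 1 ~ "shoot",
          .data$bh_q <= enrich_q & .data$odds_ratio < 1 ~ "leaf",
          TRUE ~ "none")) |>
      dplyr::select("cluster_id", "odds_ratio", "fisher_p", "bh_q",
                    "enrichment")
    comp <- dplyr::left_join(comp, stats_tbl, by = "cluster_id")
  } else {
    comp$odds_ratio <- NA_real_
    comp$fisher_p <- NA_real_
    comp$bh_q <- NA_real_
    comp$enrichment <- NA_character_
  }
  dplyr::arrange(comp, .data$cluster_id, .data$sample_id)
}

#' Correlation between cluster mean-expression profiles
#'
#' Pearson correlation of the per-cluster mean log-normalized expression
#' vectors over all genes. Closely related clusters (e.g. subpopulations of
#' one cell type) show correlations near 1.
#'
#' @param ds An [sc_dataset()] with a lognorm layer and at least two clusters.
#' @return A symmetric cluster-by-cluster correlation matrix with unit
#'   diagonal.
#' @export
cluster_correlation <- function(ds) {
  X <- get_lognorm(ds, "cluster_correlation")
  cl <- ds$cells$cluster_id
  keep <- !is.na(cl)
  cl <- cl[keep]
  clusters <- sort(unique(cl))
  if (length(clusters) < 2) {
    stop("cluster_correlation needs at least 2 clusters", call. = FALSE)
  }
  means <- vapply(clusters, function(k) {
    idx <- which(keep)[cl == k]
    if (length(idx) == 0) stop("cluster ", k, " has no cells", call. = FALSE)
    Matrix::rowSums(X[, idx, drop = FALSE]) / length(idx)
  }, numeric(nrow(X)))
  colnames(means) <- as.character(clusters)
  stats::cor(means)
}

#' Annotate clusters from known marker genes
#'
#' Scores each (cluster, cell type) pair as the mean, over the type's marker
#' genes, of the across-cluster z-score of the cluster's mean log-normalized
#' expression; a cluster is assigned the argmax cell type when its score is
#' positive and "unknown" otherwise. Exact ties go to the lexicographically
#' first cell type and are recorded. Also emits dot-plot statistics (mean
#' expression and fraction of expressing cells) for every marker and cluster.
#'
#' @param ds An [sc_dataset()] with a lognorm layer and cluster labels.
#' @param marker_table Data frame with columns `cell_type` and `gene_id`
#'   mapping cell types to known marker genes. Genes absent from the matrix
#'   are skipped with a warning; a cell type whose markers are all absent is
#'   unscorable.
#' @return A list of class `sc_annotation`: `assignments` (tibble of
#'   `cluster_id`, `cell_type`, `score`, `tie`), `scores` (cluster x type
#'   tibble) and `dotplot` (tibble of `gene_id`, `cell_type`, `cluster_id`,
#'   `mean_expr`, `frac_expressing`).
#' @export
annotate_clusters <- function(ds, marker_table) {
  X <- get_lognorm(ds, "annotate_clusters")
  marker_table <- as_tibble(marker_table)
  stopifnot(all(c("cell_type", "gene_id") %in% names(marker_table)))
  absent <- setdiff(marker_table$gene_id, rownames(X))
  if (length(absent)) {
    warning("marker genes absent from the matrix, skipped: ",
            paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    marker_table <- dplyr::filter(marker_table, !.data$gene_id %in% absent)
  }
  if (nrow(marker_table) == 0) {
    stop("no marker genes left after dropping absent ones", call. = FALSE)
  }
  cl <- ds$cells$cluster_id
  keep <- which(!is.na(cl))
  clusters <- sort(unique(cl[keep]))
  genes <- unique(marker_table$gene_id)
  gi <- match(genes, rownames(X))

  per_cluster <- purrr::map(clusters, function(k) {
    idx <- keep[cl[keep] == k]
    sub <- X[gi, idx, drop = FALSE]
    tibble(
      gene_id = genes, cluster_id = k,
      mean_expr = Matrix::rowSums(sub) / length(idx),
      frac_expressing = Matrix::rowSums(sub > 0) / length(idx))
  }) |> dplyr::bind_rows()

  dotplot <- dplyr::left_join(marker_table, per_cluster, by = "gene_id",
                              relationship = "many-to-many")

  # z-score each marker's cluster means across clusters
  zs <- per_cluster |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(z = if (stats::sd(.data$mean_expr) > 0) {
      (.data$mean_expr - mean(.data$mean_expr)) / stats::sd(.data$mean_expr)
    } else 0) |>
    dplyr::ungroup()
  scores <- dplyr::left_join(marker_table, zs, by = "gene_id",
                             relationship = "many-to-many") |>
    dplyr::group_by(.data$cluster_id, .data$cell_type) |>
    dplyr::summarise(score = mean(.data$z), .groups = "drop")

  assignments <- scores |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$cell_type,
                   .by_group = TRUE) |>
    dplyr::summarise(
      assigned = if (.data$score[1] > 0) .data$cell_type[1] else "unknown",
      top_score = .data$score[1],
      tie = sum(.data$score == .data$score[1]) > 1,
      .groups = "drop") |>
    dplyr::select("cluster_id", cell_type = "assigned",
                  score = "top_score", "tie")

  structure(list(assignments = assignments, scores = scores,
                 dotplot = dotplot),
            class = "sc_annotation")
}

#' @export
print.sc_annotation <- function(x, ...) {
  cat("<sc_annotation>\n")
  print(x$assignments)
  invisible(x)
}

#' Apply cluster annotation to the cells table
#'
#' @param ds An [sc_dataset()].
#' @param annotation An `sc_annotation` from [annotate_clusters()], or a data
#'   frame with `cluster_id` and `cell_type`.
#' @return The dataset with `cell_type` filled from the cluster assignment.
#' @export
set_cell_types <- function(ds, annotation) {
  if (inherits(annotation, "sc_annotation")) {
    annotation <- annotation$assignments
  }
  idx <- match(ds$cells$cluster_id, annotation$cluster_id)
  ds$cells$cell_type <- annotation$cell_type[idx]
  ds
}
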