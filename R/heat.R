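# Control-vs-heat differential expression per cell type and derived analyses:
# shared/specific DEG partition, single-type heat markers, opposite-pattern
# genes, UMI depth shift, reference-gene stability, subgenome DEG counts and
# gene-family summaries.

#' Heat-stress DEGs within one cell type
#'
#' Tests every gene heat-versus-control within the cell type with the
#' [hurdle_test()], and keeps genes with `|log2FC| >= heat_log2fc` (0.36,
#' heat minus control), raw `p < heat_p` (0.05) and detection in more than
#' `heat_target_frac` (25%) of the type's cells, pooled across conditions.
#' Direction follows the sign of the fold change. Set `adjust = TRUE` to gate
#' on BH q instead of raw p.
#'
#' @param ds An [sc_dataset()] with lognorm layer, cell-type labels and both
#'   conditions; each condition needs at least 3 cells of the type.
#' @param cell_type One cell-type label.
#' @param adjust Gate on BH-adjusted q instead of raw p.
#' @return A tibble of DEGs: `cell_type`, `gene_id`, `log2fc`, `p`, `q`,
#'   `pct_heat`, `pct_control`, `pct_type`, `direction` ("up"/"down").
#' @export
condition_degs <- function(ds, cell_type, adjust = FALSE) {
  X <- get_lognorm(ds, "condition_degs")
  th <- ds$thresholds
  idx <- type_cells_idx(ds, cell_type)
  cond <- ds$cells$condition[idx]
  heat <- idx[cond == "heat"]
  ctrl <- idx[cond == "control"]
  if (length(heat) < 3 || length(ctrl) < 3) {
    stop("cell type '", cell_type,
         "' needs >= 3 cells in each condition (heat: ", length(heat),
         ", control: ", length(ctrl), ")", call. = FALSE)
  }
  res <- de_test(ds, heat, ctrl, adjust = TRUE)
  pct_type <- as.numeric(
    Matrix::rowSums(X[, idx, drop = FALSE] > 0) / length(idx))
  gate_p <- if (adjust) res$q else res$p
  res |>
    dplyr::mutate(cell_type = cell_type, pct_type = pct_type,
                  gate_p = gate_p) |>
    dplyr::filter(abs(.data$log2fc) >= th$heat_log2fc,
                  .data$gate_p < th$heat_p,
                  .data$pct_type > th$heat_target_frac) |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    dplyr::select(cell_type = "cell_type", gene_id = "gene_id",
                  log2fc = "log2fc", p = "p", q = "q",
                  pct_heat = "pct_a", pct_control = "pct_b",
                  pct_type = "pct_type", direction = "direction")
}

#' @rdname condition_degs
#' @param cell_types Types to analyse (default: all labeled types with both
#'   conditions).
#' @return `heat_deg_table()`: the row-bound tibble over cell types.
#' @export
heat_deg_table <- function(ds, cell_types = NULL, adjust = FALSE) {
  if (is.null(cell_types)) {
    ct <- ds$cells$cell_type
    cell_types <- sort(unique(ct[!is.na(ct) & ct != "unknown"]))
  }
  purrr::map(cell_types, condition_degs, ds = ds, adjust = adjust) |>
    dplyr::bind_rows()
}

#' Partition DEGs by the cell-type subsets they occur in
#'
#' UpSet-style exact partition: per direction, every DEG is assigned to the
#' set of cell types in which it was called with that direction. Derived
#' fields give the genes shared by all analysed types, the single-type
#' specific genes, and the genes appearing with both directions (opposite
#' pattern).
#'
#' @param heat_table A tibble from [heat_deg_table()] covering >= 2 cell
#'   types.
#' @param cell_types The full set of analysed types (default: those in the
#'   table).
#' @return An object of class `sc_deg_partition`: `membership` (tibble of
#'   `direction`, `subset` ("+"-joined sorted types), `n_types`, `gene_id`),
#'   `shared_all` and `specific` (per direction), `opposite` (gene ids),
#'   `cell_types`.
#' @export
deg_partition <- function(heat_table, cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- sort(unique(heat_table$cell_type))
  if (length(cell_types) < 2) {
    stop("deg_partition needs DEGs computed for >= 2 cell types",
         call. = FALSE)
  }
  membership <- heat_table |>
    dplyr::group_by(.data$direction, .data$gene_id) |>
    dplyr::summarise(
      subset = paste(sort(unique(.data$cell_type)), collapse = "+"),
      n_types = length(unique(.data$cell_type)), .groups = "drop") |>
    dplyr::select("direction", "subset", "n_types", "gene_id") |>
    dplyr::arrange(.data$direction, dplyr::desc(.data$n_types), .data$subset,
                   .data$gene_id)
  all_key <- paste(sort(cell_types), collapse = "+")
  shared_all <- purrr::map(c(up = "up", down = "down"), function(d) {
    membership$gene_id[membership$direction == d &
                         membership$subset == all_key]
  })
  specific <- purrr::map(c(up = "up", down = "down"), function(d) {
    m <- membership[membership$direction == d & membership$n_types == 1, ]
    split(m$gene_id, factor(m$subset, levels = cell_types))
  })
  both <- intersect(membership$gene_id[membership$direction == "up"],
                    membership$gene_id[membership$direction == "down"])
  structure(list(membership = membership, shared_all = shared_all,
                 specific = specific, opposite = both,
                 cell_types = cell_types),
            class = "sc_deg_partition")
}

#' @export
print.sc_deg_partition <- function(x, ...) {
  cat("<sc_deg_partition> over", length(x$cell_types), "cell types\n")
  cat("  shared in all types: up", length(x$shared_all$up), "/ down",
      length(x$shared_all$down), "\n")
  cat("  single-type specific: up", sum(lengths(x$specific$up)), "/ down",
      sum(lengths(x$specific$down)), "\n")
  cat("  opposite-direction genes:", length(x$opposite), "\n")
  invisible(x)
}

#' @rdname deg_partition
#' @param x An `sc_deg_partition`.
#' @param ... Unused.
#' @export
tidy.sc_deg_partition <- function(x, ...) {
  x$membership
}

#' Heat-stress response marker genes
#'
#' Genes that are differentially expressed (in either direction) in exactly
#' one cell type. A gene up in one type and down in another touches two types
#' and is excluded.
#'
#' @param partition An `sc_deg_partition` from [deg_partition()].
#' @return A tibble: `cell_type`, `gene_id`, `direction`.
#' @export
heat_marker_genes <- function(partition) {
  stopifnot(inherits(partition, "sc_deg_partition"))
  m <- partition$membership
  span <- m |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      types = paste(sort(unique(unlist(strsplit(.data$subset, "+",
                                                fixed = TRUE)))),
                    collapse = "+"),
      n_types_any = length(unique(unlist(strsplit(.data$subset, "+",
                                                  fixed = TRUE)))),
      .groups = "drop")
  single <- span$gene_id[span$n_types_any == 1]
  m |>
    dplyr::filter(.data$gene_id %in% single, .data$n_types == 1) |>
    dplyr::select(cell_type = "subset", gene_id = "gene_id",
                  direction = "direction") |>
    dplyr::arrange(.data$cell_type, .data$gene_id)
}

#' Genes with opposite heat responses across cell types
#'
#' Genes called as an up-DEG in at least one cell type and a down-DEG in at
#' least one other, reported for every type where they are differentially
#' expressed together with the per-type sign.
#'
#' @param heat_table A tibble from [heat_deg_table()] over >= 2 cell types.
#' @return A tibble: `gene_id`, `cell_type`, `direction`.
#' @export
opposite_pattern_genes <- function(heat_table) {
  if (length(unique(heat_table$cell_type)) < 2) {
    stop("opposite_pattern_genes needs >= 2 cell types", call. = FALSE)
  }
  dirs <- heat_table |>
    dplyr::distinct(.data$gene_id, .data$direction)
  both <- dirs |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n == 2) |>
    dplyr::pull(.data$gene_id)
  heat_table |>
    dplyr::filter(.data$gene_id %in% both) |>
    dplyr::select("gene_id", "cell_type", "direction") |>
    dplyr::arrange(.data$gene_id, .data$cell_type)
}

#' Per-cell UMI depth shift under heat
#'
#' Compares per-cell total UMI counts between heat and control cells of a cell
#' type with a two-sided Wilcoxon rank-sum test and reports the condition
#' medians.
#'
#' @param ds An [sc_dataset()] with raw counts and both conditions present in
#'   the type.
#' @param cell_type One cell-type label, or `NULL` for all labeled types.
#' @return A tibble: `cell_type`, `n_control`, `n_heat`, `median_control`,
#'   `median_heat`, `p`.
#' @export
umi_shift_test <- function(ds, cell_type = NULL) {
  if (is.null(cell_type)) {
    ct <- ds$cells$cell_type
    types <- sort(unique(ct[!is.na(ct) & ct != "unknown"]))
    return(dplyr::bind_rows(purrr::map(types, umi_shift_test, ds = ds)))
  }
  idx <- type_cells_idx(ds, cell_type)
  totals <- Matrix::colSums(ds$counts[, idx, drop = FALSE])
  cond <- ds$cells$condition[idx]
  if (!all(c("control", "heat") %in% cond)) {
    stop("cell type '", cell_type, "' lacks one of the conditions",
         call. = FALSE)
  }
  ctrl <- totals[cond == "control"]
  heat <- totals[cond == "heat"]
  p <- stats::wilcox.test(heat, ctrl, alternative = "two.sided",
                          exact = FALSE)$p.value
  tibble(cell_type = cell_type,
         n_control = length(ctrl), n_heat = length(heat),
         median_control = stats::median(ctrl),
         median_heat = stats::median(heat), p = p)
}

#' Reference-gene stability check
#'
#' Flags, per reference gene and cell type, whether the gene stayed out of the
#' heat DEG table ("pass") or was called ("fail"); genes absent from the
#' matrix are "untestable". The overall verdict (attribute `overall_pass`,
#' also from [glance()]) is pass iff every testable entry passes.
#'
#' @param heat_table A tibble from [heat_deg_table()].
#' @param reference_ids Character vector of reference gene ids.
#' @param gene_ids The dataset's gene universe (e.g. `ds$genes$gene_id`).
#' @param cell_types Types covered by the DEG analysis (default: those in the
#'   table).
#' @return A tibble of class `sc_reference_check`: `gene_id`, `cell_type`,
#'   `status` ("pass"/"fail"/"untestable").
#' @export
reference_gene_check <- function(heat_table, reference_ids, gene_ids,
                                 cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- sort(unique(heat_table$cell_type))
  if (length(reference_ids) == 0) {
    warning("empty reference gene list: vacuous pass", call. = FALSE)
    out <- tibble(gene_id = character(), cell_type = character(),
                  status = character())
    attr(out, "overall_pass") <- TRUE
    class(out) <- c("sc_reference_check", class(out))
    return(out)
  }
  grid <- tidyr::expand_grid(gene_id = reference_ids, cell_type = cell_types)
  deg_key <- paste(heat_table$gene_id, heat_table$cell_type)
  grid$status <- dplyr::case_when(
    !grid$gene_id %in% gene_ids ~ "untestable",
    paste(grid$gene_id, grid$cell_type) %in% deg_key ~ "fail",
    TRUE ~ "pass")
  attr(grid, "overall_pass") <- !any(grid$status == "fail")
  class(grid) <- c("sc_reference_check", class(grid))
  grid
}

#' @rdname reference_gene_check
#' @param x An `sc_reference_check`.
#' @param ... Unused.
#' @export
glance.sc_reference_check <- function(x, ...) {
  tibble(n_reference = length(unique(x$gene_id)),
         n_fail = sum(x$status == "fail"),
         n_untestable = sum(x$status == "untestable"),
         overall_pass = isTRUE(attr(x, "overall_pass")))
}

#' Heat DEG counts per subgenome
#'
#' Counts DEGs per cell type and subgenome, overall and split by direction.
#'
#' @param heat_table A tibble from [heat_deg_table()].
#' @param genes Gene annotation table (`gene_id`, `subgenome`).
#' @return A tibble: `cell_type`, `subgenome`, `n_up`, `n_down`, `n_total`
#'   (zeros kept).
#' @export
subgenome_deg_counts <- function(heat_table, genes) {
  heat_table$subgenome <- genes$subgenome[match(heat_table$gene_id,
                                                genes$gene_id)]
  out <- heat_table |>
    dplyr::count(.data$cell_type, .data$subgenome, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       names_prefix = "n_", values_fill = 0L) |>
    tidyr::complete(cell_type = unique(heat_table$cell_type),
                    subgenome = subgenome_levels,
                    fill = list(n_up = 0L, n_down = 0L))
  for (col in c("n_up", "n_down")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]] <- tidyr::replace_na(out[[col]], 0L)
  }
  out |>
    dplyr::mutate(n_total = .data$n_up + .data$n_down) |>
    dplyr::select("cell_type", "subgenome", "n_up", "n_down", "n_total") |>
    dplyr::arrange(.data$cell_type,
                   factor(.data$subgenome, levels = subgenome_levels))
}

#' Per-family heat-response direction matrix
#'
#' For every member of a tagged gene family, the heat response per cell type:
#' "up", "down" or "ns" (not significant). The syntelog group and subgenome
#' are carried so copy-divergent responses within a family are visible.
#'
#' @param heat_table A tibble from [heat_deg_table()].
#' @param genes Gene annotation table with `gene_id`, `subgenome`,
#'   `syntelog_group` and `family`.
#' @param family_tag Family label to summarise (e.g. "HSP").
#' @param cell_types Types covered by the analysis (default: those in the
#'   table).
#' @return A tibble: `gene_id`, `subgenome`, `syntelog_group`, `cell_type`,
#'   `status`.
#' @export
family_summary <- function(heat_table, genes, family_tag, cell_types = NULL) {
  fams <- unique(genes$family[!is.na(genes$family)])
  if (!family_tag %in% fams) {
    stop("unknown family tag '", family_tag, "'; available: ",
         if (length(fams)) paste(fams, collapse = ", ") else "(none)",
         call. = FALSE)
  }
  if (is.null(cell_types)) cell_types <- sort(unique(heat_table$cell_type))
  members <- genes[!is.na(genes$family) & genes$family == family_tag,
                   c("gene_id", "subgenome", "syntelog_group")]
  grid <- tidyr::expand_grid(gene_id = members$gene_id,
                             cell_type = cell_types) |>
    dplyr::left_join(members, by = "gene_id") |>
    dplyr::left_join(
      heat_table[, c("gene_id", "cell_type", "direction")],
      by = c("gene_id", "cell_type")) |>
    dplyr::mutate(status = tidyr::replace_na(.data$direction, "ns"),
                  direction = NULL)
  dplyr::arrange(grid[, c("gene_id", "subgenome", "syntelog_group",
                          "cell_type", "status")],
                 .data$syntelog_group, .data$subgenome, .data$cell_type)
}
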