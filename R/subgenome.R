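# Expressed-gene sets per cell type, subgenome expression proportions,
# copy-class statistics and predominant-expression (dominance) calls among
# syntelog copies.

type_cells_idx <- function(ds, cell_type) {
  ct <- ds$cells$cell_type
  idx <- which(!is.na(ct) & ct == cell_type)
  if (length(idx) == 0) {
    stop("no cells labeled as cell type '", cell_type, "'", call. = FALSE)
  }
  idx
}

#' Genes expressed in a cell type
#'
#' A gene counts as expressed in a cell type when it has a nonzero raw count
#' in at least `expressed_cell_frac` (default 5%) of the type's cells; the
#' boundary is inclusive.
#'
#' @param ds An [sc_dataset()] with `cell_type` labels.
#' @param cell_type A single cell-type label present in the dataset.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(ds, cell_type) {
  idx <- type_cells_idx(ds, cell_type)
  frac <- Matrix::rowSums(ds$counts[, idx, drop = FALSE] > 0) / length(idx)
  rownames(ds$counts)[frac >= ds$thresholds$expressed_cell_frac]
}

#' @rdname expressed_genes
#' @param cell_types Types to tabulate (default all labeled, "unknown"
#'   excluded).
#' @return `expressed_gene_sets()`: a long tibble (`cell_type`, `gene_id`).
#' @export
expressed_gene_sets <- function(ds, cell_types = NULL) {
  if (is.null(cell_types)) {
    ct <- ds$cells$cell_type
    cell_types <- sort(unique(ct[!is.na(ct) & ct != "unknown"]))
  }
  purrr::map(cell_types, function(t) {
    tibble(cell_type = t, gene_id = expressed_genes(ds, t))
  }) |> dplyr::bind_rows()
}

#' Subgenome share of expressed genes per cell type
#'
#' Tabulates, for each cell type, how many expressed genes fall in each
#' subgenome (LF/MF1/MF2/UG), their proportion of the type's expressed genes,
#' and the mean log-normalized expression over the type's cells and the
#' subgenome's expressed genes.
#'
#' @param ds An [sc_dataset()] with a lognorm layer and cell-type labels.
#' @param expressed Optional precomputed [expressed_gene_sets()] tibble.
#' @return A tibble: `cell_type`, `subgenome`, `n_expressed`, `proportion`,
#'   `mean_expr`. Proportions sum to 1 within each cell type.
#' @export
subgenome_proportions <- function(ds, expressed = NULL) {
  X <- get_lognorm(ds, "subgenome_proportions")
  if (is.null(expressed)) expressed <- expressed_gene_sets(ds)
  if (nrow(expressed) == 0) stop("empty expressed gene set", call. = FALSE)
  sg <- ds$genes$subgenome[match(expressed$gene_id, ds$genes$gene_id)]
  expressed$subgenome <- sg
  counts <- expressed |>
    dplyr::count(.data$cell_type, .data$subgenome, name = "n_expressed") |>
    tidyr::complete(cell_type = unique(expressed$cell_type),
                    subgenome = subgenome_levels,
                    fill = list(n_expressed = 0L)) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(proportion = .data$n_expressed / sum(.data$n_expressed)) |>
    dplyr::ungroup()
  counts$mean_expr <- purrr::pmap_dbl(
    counts[, c("cell_type", "subgenome", "n_expressed")],
    function(cell_type, subgenome, n_expressed) {
      if (n_expressed == 0) return(NA_real_)
      g <- expressed$gene_id[expressed$cell_type == cell_type &
                               expressed$subgenome == subgenome]
      idx <- type_cells_idx(ds, cell_type)
      sub <- X[match(g, rownames(X)), idx, drop = FALSE]
      sum(sub) / (length(g) * length(idx))
    })
  counts$subgenome <- factor(counts$subgenome, levels = subgenome_levels)
  dplyr::arrange(counts, .data$cell_type, .data$subgenome)
}

#' Expressed fraction by syntelog copy class
#'
#' For each cell type, the fraction of genes expressed within each copy class
#' (1:1, 1:2, 1:3) and among the ungrouped (UG) genes. Empty classes yield an
#' `NA` fraction rather than 0.
#'
#' @inheritParams subgenome_proportions
#' @return A tibble: `cell_type`, `copy_class` ("1:1", "1:2", "1:3", "UG"),
#'   `n_genes`, `n_expressed`, `fraction`.
#' @export
copy_class_expression <- function(ds, expressed = NULL) {
  if (is.null(ds$syntelogs)) {
    stop("dataset carries no syntelog table", call. = FALSE)
  }
  if (is.null(expressed)) expressed <- expressed_gene_sets(ds)
  class_of <- stats::setNames(
    paste0("1:", ds$syntelogs$copy_class), ds$syntelogs$gene_id)
  ug <- ds$genes$gene_id[ds$genes$subgenome == "UG"]
  class_of[ug] <- "UG"
  universe <- tibble(gene_id = names(class_of),
                     copy_class = unname(class_of))
  sizes <- dplyr::count(universe, .data$copy_class, name = "n_genes")
  expressed |>
    dplyr::mutate(copy_class = class_of[.data$gene_id]) |>
    dplyr::filter(!is.na(.data$copy_class)) |>
    dplyr::count(.data$cell_type, .data$copy_class, name = "n_expressed") |>
    tidyr::complete(cell_type = unique(expressed$cell_type),
                    copy_class = c("1:1", "1:2", "1:3", "UG"),
                    fill = list(n_expressed = 0L)) |>
    dplyr::left_join(sizes, by = "copy_class") |>
    dplyr::mutate(
      n_genes = tidyr::replace_na(.data$n_genes, 0L),
      fraction = ifelse(.data$n_genes > 0,
                        .data$n_expressed / .data$n_genes, NA_real_)) |>
    dplyr::select("cell_type", "copy_class", "n_genes", "n_expressed",
                  "fraction") |>
    dplyr::arrange(.data$cell_type, .data$copy_class)
}

# Dominance ---------------------------------------------------------------

dominance_call_group <- function(Xg, pct, genes_sg, th, test) {
  k <- nrow(Xg)
  ids <- rownames(Xg)
  pair_fc <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  pair_p <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      fc <- fold_change(Xg[i, ], Xg[j, ])
      p <- if (test == "signed_rank") {
        paired_signed_rank(Xg[i, ], Xg[j, ])
      } else {
        hurdle_test(Xg[i, ], Xg[j, ])
      }
      pair_fc[i, j] <- fc
      pair_fc[j, i] <- -fc
      pair_p[i, j] <- p
      pair_p[j, i] <- p
    }
  }
  winner <- NA_integer_
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(k), i)
    if (pct[i] >= th$expressed_cell_frac &&
        all(pair_fc[i, others] >= th$dominance_log2fc) &&
        all(pair_p[i, others] <= th$dominance_p)) {
      winner <- i
      break
    }
  }
  list(
    winner_gene = if (is.na(winner)) NA_character_ else ids[winner],
    winner_sg = if (is.na(winner)) NA_character_ else genes_sg[winner],
    pairs = tibble(
      copy_i = ids[rep(seq_len(k - 1), times = (k - 1):1)],
      copy_j = ids[unlist(lapply(seq_len(k - 1), function(i) (i + 1):k))],
      log2fc = pair_fc[upper.tri(pair_fc)],
      p = pair_p[upper.tri(pair_p)]
    )
  )
}

#' Subgenome dominance calls over syntelog groups
#'
#' Within each cell type and multi-copy syntelog group, the homoeologous
#' copies are compared pairwise over the same cells: the log2 fold change uses
#' [fold_change()] on the lognorm values and the p-value a paired
#' [paired_signed_rank()] test (the copies are measured in identical cells;
#' `test = "hurdle"` selects the unpaired hurdle test instead). A copy is
#' called dominant iff it is detected in at least `expressed_cell_frac` (5%)
#' of the type's cells and beats every other copy with log2FC >=
#' `dominance_log2fc` (0.36) and p <= `dominance_p` (0.05). At most one copy
#' can win; otherwise the group's call is none (`NA`). P-values are reported
#' raw, as in the threshold rule.
#'
#' @param ds An [sc_dataset()] with lognorm layer, cell-type labels and a
#'   syntelog table.
#' @param cell_types Cell types to analyse (default: all labeled).
#' @param groups Syntelog group ids (default: all multi-copy groups).
#' @param test Pairwise test: `"signed_rank"` (paired, default) or
#'   `"hurdle"`.
#' @return A tibble with one row per (group, cell type): `group_id`,
#'   `cell_type`, `copy_class`, `dominant_gene`, `dominant_subgenome` (`NA`
#'   when no copy wins).
#' @export
dominance_calls <- function(ds, cell_types = NULL, groups = NULL,
                            test = c("signed_rank", "hurdle")) {
  test <- match.arg(test)
  X <- get_lognorm(ds, "dominance_calls")
  if (is.null(ds$syntelogs)) {
    stop("dataset carries no syntelog table", call. = FALSE)
  }
  th <- ds$thresholds
  syn <- ds$syntelogs
  if (is.null(groups)) {
    groups <- unique(syn$group_id[syn$copy_class >= 2])
  }
  single <- setdiff(groups, syn$group_id[syn$copy_class >= 2])
  if (length(single)) {
    stop("dominance requires multi-copy groups; single-copy: ",
         paste(utils::head(single, 3), collapse = ", "), call. = FALSE)
  }
  if (is.null(cell_types)) {
    ct <- ds$cells$cell_type
    cell_types <- sort(unique(ct[!is.na(ct) & ct != "unknown"]))
  }
  syn <- syn[syn$group_id %in% groups, ]
  gene_rows <- match(syn$gene_id, rownames(X))

  purrr::map(cell_types, function(t) {
    idx <- type_cells_idx(ds, t)
    sub <- as.matrix(X[gene_rows, idx, drop = FALSE])
    rownames(sub) <- syn$gene_id
    pct_all <- Matrix::rowSums(ds$counts[gene_rows, idx, drop = FALSE] > 0) /
      length(idx)
    names(pct_all) <- syn$gene_id
    split_idx <- split(seq_len(nrow(syn)), syn$group_id)
    purrr::imap(split_idx, function(rows, g) {
      res <- dominance_call_group(sub[rows, , drop = FALSE],
                                  pct_all[rows], syn$subgenome[rows],
                                  th, test)
      tibble(group_id = g, cell_type = t,
             copy_class = length(rows),
             dominant_gene = res$winner_gene,
             dominant_subgenome = res$winner_sg)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Single-group dominance call with pairwise detail
#'
#' @inheritParams dominance_calls
#' @param group One multi-copy syntelog group id.
#' @param cell_type One cell-type label.
#' @return A list: `call` (one-row tibble as in [dominance_calls()]) and
#'   `pairs` (tibble of pairwise `copy_i`, `copy_j`, `log2fc`, `p`).
#' @export
dominance_call <- function(ds, group, cell_type,
                           test = c("signed_rank", "hurdle")) {
  test <- match.arg(test)
  X <- get_lognorm(ds, "dominance_call")
  syn <- ds$syntelogs[ds$syntelogs$group_id == group, ]
  if (nrow(syn) == 0) stop("unknown syntelog group: ", group, call. = FALSE)
  if (nrow(syn) < 2) {
    stop("dominance requires a multi-copy group; '", group,
         "' has a single copy", call. = FALSE)
  }
  idx <- type_cells_idx(ds, cell_type)
  rows <- match(syn$gene_id, rownames(X))
  sub <- as.matrix(X[rows, idx, drop = FALSE])
  rownames(sub) <- syn$gene_id
  pct <- Matrix::rowSums(ds$counts[rows, idx, drop = FALSE] > 0) / length(idx)
  res <- dominance_call_group(sub, pct, syn$subgenome, ds$thresholds, test)
  list(
    call = tibble(group_id = group, cell_type = cell_type,
                  copy_class = nrow(syn),
                  dominant_gene = res$winner_gene,
                  dominant_subgenome = res$winner_sg),
    pairs = res$pairs
  )
}

#' Dominance counts per cell type and subgenome
#'
#' Counts, per cell type, the syntelog groups whose dominant copy lies in each
#' subgenome; groups without a winner are excluded.
#'
#' @param calls A tibble from [dominance_calls()].
#' @return A tibble: `cell_type`, `subgenome` (LF/MF1/MF2), `n` (zeros kept).
#' @export
dominance_counts <- function(calls) {
  calls |>
    dplyr::filter(!is.na(.data$dominant_subgenome)) |>
    dplyr::count(.data$cell_type, subgenome = .data$dominant_subgenome) |>
    tidyr::complete(cell_type = unique(calls$cell_type),
                    subgenome = c("LF", "MF1", "MF2"),
                    fill = list(n = 0L)) |>
    dplyr::arrange(.data$cell_type, .data$subgenome)
}
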