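#' @importFrom Matrix readMM writeMM rowSums colSums t sparseMatrix
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# Controlled vocabularies ------------------------------------------------

subgenome_levels <- c("LF", "MF1", "MF2", "UG")
tissue_levels <- c("shoot", "leaf")
condition_levels <- c("control", "heat")
cell_type_levels <- c("meristem", "mesophyll", "proliferating",
                      "epidermal", "guard", "vascular", "unknown")

#' Assemble a single-cell dataset
#'
#' Container for a genes-by-cells UMI matrix, per-cell and per-gene annotation
#' tables, an optional syntelog table and the analysis thresholds. The counts
#' matrix stays sparse throughout; a log-normalized layer is added by
#' [log_normalize()].
#'
#' @param counts A genes x cells sparse (or coercible) matrix of non-negative
#'   integer UMI counts with unique rownames (gene ids) and colnames (cell
#'   barcodes).
#' @param cells A data frame with one row per barcode: `barcode`, `sample_id`,
#'   `tissue` ("shoot"/"leaf"), `condition` ("control"/"heat"), and optional
#'   `cluster_id` (non-negative integer) and `cell_type`.
#' @param genes A data frame with one row per gene: `gene_id`, `subgenome`
#'   ("LF"/"MF1"/"MF2"/"UG"), and optional `syntelog_group`, `at_ortholog`,
#'   `family`.
#' @param syntelogs Optional syntelog table as built by
#'   [build_syntelog_table()]; built from `genes` when `NULL` and any
#'   syntelog groups are annotated.
#' @param thresholds An [sc_thresholds()] bundle.
#' @param lognorm Optional pre-computed log-normalized layer (same dims as
#'   `counts`).
#'
#' @return An object of class `sc_dataset`: a list with elements `counts`,
#'   `lognorm` (possibly `NULL`), `cells`, `genes`, `syntelogs`, `thresholds`.
#' @export
sc_dataset <- function(counts, cells, genes, syntelogs = NULL,
                       thresholds = sc_thresholds(), lognorm = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids as rownames and barcodes as colnames",
         call. = FALSE)
  }
  cells <- as_tibble(cells)
  genes <- as_tibble(genes)
  ds <- structure(
    list(counts = counts, lognorm = lognorm, cells = cells, genes = genes,
         syntelogs = syntelogs, thresholds = thresholds),
    class = "sc_dataset"
  )
  validate_sc_dataset(ds)
  if (is.null(syntelogs) && any(!is.na(genes$syntelog_group %||% NA))) {
    ds$syntelogs <- build_syntelog_table(genes)
  }
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sc_dataset <- function(ds) {
  m <- ds$counts
  if (any(m@x < 0)) stop("counts matrix contains negative entries", call. = FALSE)
  if (any(m@x != round(m@x))) {
    stop("raw counts layer must contain integers only", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) stop("duplicate cell barcodes", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids", call. = FALSE)
  req_cell <- c("barcode", "sample_id", "tissue", "condition")
  missing_cols <- setdiff(req_cell, names(ds$cells))
  if (length(missing_cols)) {
    stop("cells table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(ds$cells$barcode, colnames(m)) ||
      nrow(ds$cells) != ncol(m)) {
    stop("cells table barcodes do not match matrix columns", call. = FALSE)
  }
  if (!all(ds$cells$tissue %in% tissue_levels)) {
    stop("tissue must be one of: ", paste(tissue_levels, collapse = ", "),
         call. = FALSE)
  }
  if (!all(ds$cells$condition %in% condition_levels)) {
    stop("condition must be one of: ", paste(condition_levels, collapse = ", "),
         call. = FALSE)
  }
  if (any(ds$cells$condition == "heat" & ds$cells$tissue != "leaf")) {
    stop("heat condition is only defined for leaf tissue", call. = FALSE)
  }
  if (!all(c("gene_id", "subgenome") %in% names(ds$genes))) {
    stop("genes table needs gene_id and subgenome columns", call. = FALSE)
  }
  if (!setequal(ds$genes$gene_id, rownames(m)) || nrow(ds$genes) != nrow(m)) {
    stop("genes table ids do not match matrix rows", call. = FALSE)
  }
  if (!all(ds$genes$subgenome %in% subgenome_levels)) {
    stop("subgenome must be one of: ", paste(subgenome_levels, collapse = ", "),
         call. = FALSE)
  }
  if ("syntelog_group" %in% names(ds$genes)) {
    ug_grouped <- ds$genes$subgenome == "UG" & !is.na(ds$genes$syntelog_group)
    if (any(ug_grouped)) {
      stop("UG genes cannot carry a syntelog_group: ",
           paste(utils::head(ds$genes$gene_id[ug_grouped], 3), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(ds)
}

# Align annotation tables to matrix order (file order is canonical).
align_dataset <- function(ds) {
  ds$cells <- ds$cells[match(colnames(ds$counts), ds$cells$barcode), ]
  ds$genes <- ds$genes[match(rownames(ds$counts), ds$genes$gene_id), ]
  ds
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat("<sc_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells\n",
      sep = "")
  cat("  layers: raw_counts",
      if (!is.null(x$lognorm)) ", lognorm" else "", "\n", sep = "")
  cat("  tissues: ", paste(sort(unique(x$cells$tissue)), collapse = "/"),
      "; conditions: ", paste(sort(unique(x$cells$condition)), collapse = "/"),
      "\n", sep = "")
  if (!is.null(x$syntelogs)) {
    cat("  syntelog groups: ", length(unique(x$syntelogs$group_id)), "\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname sc_dataset
#' @param x An `sc_dataset`.
#' @param ... Unused.
#' @export
glance.sc_dataset <- function(x, ...) {
  tibble(
    n_genes = nrow(x$counts),
    n_cells = ncol(x$counts),
    total_umi = sum(x$counts@x),
    has_lognorm = !is.null(x$lognorm),
    n_syntelog_groups = if (is.null(x$syntelogs)) 0L else
      length(unique(x$syntelogs$group_id)),
    n_cell_types = sum(!is.na(unique(x$cells$cell_type %||% NA)))
  )
}

# I/O --------------------------------------------------------------------

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Read a 10x-style dataset from disk
#'
#' Loads a MatrixMarket triplet matrix together with its features/barcodes
#' tables and the per-cell/per-gene annotation tables written by
#' [write_sc_dataset()]. File order is authoritative: genes and cells keep the
#' order of the features/barcodes files.
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `cells.tsv`, `genes.tsv` (optionally gzipped). Individual
#'   paths may be overridden.
#' @param mtx,features,barcodes,cells,genes Optional explicit paths.
#' @param thresholds An [sc_thresholds()] bundle attached to the dataset.
#'
#' @return An [sc_dataset()].
#' @export
read_sc_dataset <- function(dir = NULL, mtx = NULL, features = NULL,
                            barcodes = NULL, cells = NULL, genes = NULL,
                            thresholds = sc_thresholds()) {
  pick <- function(given, name) {
    if (!is.null(given)) return(given)
    if (is.null(dir)) stop("either `dir` or `", name, "` must be given",
                           call. = FALSE)
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(name, ext))
      if (file.exists(p)) return(p)
    }
    stop("cannot find ", name, " under ", dir, call. = FALSE)
  }
  mtx <- pick(mtx, "matrix.mtx")
  features <- pick(features, "features.tsv")
  barcodes <- pick(barcodes, "barcodes.tsv")
  cells <- pick(cells, "cells.tsv")
  genes <- pick(genes, "genes.tsv")

  m <- as(Matrix::readMM(open_maybe_gz(mtx)), "CsparseMatrix")
  feat <- readr::read_tsv(features, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()))
  bc <- readr::read_tsv(barcodes, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()))
  if (nrow(feat) != nrow(m)) {
    stop("dimension mismatch: ", features, " has ", nrow(feat),
         " entries but ", mtx, " declares ", nrow(m), " rows", call. = FALSE)
  }
  if (nrow(bc) != ncol(m)) {
    stop("dimension mismatch: ", barcodes, " has ", nrow(bc),
         " entries but ", mtx, " declares ", ncol(m), " columns",
         call. = FALSE)
  }
  if (anyDuplicated(bc[[1]])) {
    stop("duplicate barcode in ", barcodes, call. = FALSE)
  }
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    stop("negative or non-integer raw count in ", mtx, call. = FALSE)
  }
  dimnames(m) <- list(feat[[1]], bc[[1]])

  cell_tbl <- readr::read_tsv(cells, col_types = readr::cols(
    .default = readr::col_character()))
  gene_tbl <- readr::read_tsv(genes, col_types = readr::cols(
    .default = readr::col_character()))
  if (!"cluster_id" %in% names(cell_tbl)) cell_tbl$cluster_id <- NA_integer_
  cell_tbl$cluster_id <- as.integer(cell_tbl$cluster_id)
  if (!"cell_type" %in% names(cell_tbl)) cell_tbl$cell_type <- NA_character_
  for (col in c("syntelog_group", "at_ortholog", "family")) {
    if (!col %in% names(gene_tbl)) gene_tbl[[col]] <- NA_character_
  }
  ds <- sc_dataset(m, cell_tbl, gene_tbl, thresholds = thresholds)
  align_dataset(ds)
}

#' Write a dataset as MatrixMarket plus TSV tables
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv`, `cells.tsv` and
#' `genes.tsv` into `out_dir`. Output is deterministic for a fixed dataset, and
#' [read_sc_dataset()] round-trips it exactly (integer counts, canonical file
#' order).
#'
#' @param ds An [sc_dataset()].
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_sc_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (ncol(ds$counts) == 0 || nrow(ds$counts) == 0) {
    stop("refusing to write a dataset with zero genes or zero cells",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- align_dataset(ds)
  paths <- c(
    mtx = file.path(out_dir, "matrix.mtx"),
    features = file.path(out_dir, "features.tsv"),
    barcodes = file.path(out_dir, "barcodes.tsv"),
    cells = file.path(out_dir, "cells.tsv"),
    genes = file.path(out_dir, "genes.tsv")
  )
  Matrix::writeMM(ds$counts, paths[["mtx"]])
  writeLines(rownames(ds$counts), paths[["features"]])
  writeLines(colnames(ds$counts), paths[["barcodes"]])
  cells <- ds$cells[, c("barcode", "sample_id", "tissue", "condition",
                        "cluster_id", "cell_type")]
  readr::write_tsv(cells, paths[["cells"]])
  gene_cols <- intersect(c("gene_id", "subgenome", "syntelog_group",
                           "at_ortholog", "family"), names(ds$genes))
  readr::write_tsv(ds$genes[, gene_cols], paths[["genes"]])
  invisible(paths)
}

# Syntelogs ---------------------------------------------------------------

#' Build the syntelog group table from gene annotations
#'
#' Groups the non-UG genes by their annotated syntelog group. Each group holds
#' 1-3 retained homoeologous copies, at most one per subgenome (LF/MF1/MF2),
#' all syntenic to one Arabidopsis gene; the copy class (1:1, 1:2, 1:3) is the
#' member count. Ungrouped (UG) genes have no syntenic ortholog and never
#' appear in the table.
#'
#' @param genes Gene annotation table (`gene_id`, `subgenome`,
#'   `syntelog_group`, `at_ortholog`).
#' @return A tibble with one row per copy: `group_id`, `at_gene`, `gene_id`,
#'   `subgenome`, `copy_class`.
#' @export
build_syntelog_table <- function(genes) {
  genes <- as_tibble(genes)
  syn <- dplyr::filter(genes, .data$subgenome != "UG")
  ug_grouped <- genes$subgenome == "UG" & !is.na(genes$syntelog_group)
  if (any(ug_grouped)) {
    stop("UG genes cannot carry a syntelog_group: ",
         paste(utils::head(genes$gene_id[ug_grouped], 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(syn$syntelog_group)) || any(is.na(syn$at_ortholog))) {
    stop("every non-UG gene must carry syntelog_group and at_ortholog",
         call. = FALSE)
  }
  tbl <- syn |>
    dplyr::group_by(group_id = .data$syntelog_group) |>
    dplyr::mutate(copy_class = dplyr::n(),
                  at_gene = .data$at_ortholog[1]) |>
    dplyr::ungroup() |>
    dplyr::select("group_id", "at_gene", "gene_id", "subgenome", "copy_class")
  bad_size <- unique(tbl$group_id[tbl$copy_class > 3])
  if (length(bad_size)) {
    stop("syntelog groups with more than 3 copies: ",
         paste(utils::head(bad_size, 3), collapse = ", "), call. = FALSE)
  }
  dup <- tbl |>
    dplyr::count(.data$group_id, .data$subgenome) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("syntelog group with two copies in one subgenome: ",
         paste(utils::head(unique(dup$group_id), 3), collapse = ", "),
         call. = FALSE)
  }
  at_conflict <- syn |>
    dplyr::distinct(.data$syntelog_group, .data$at_ortholog) |>
    dplyr::count(.data$syntelog_group) |>
    dplyr::filter(.data$n > 1)
  if (nrow(at_conflict)) {
    stop("syntelog group mapping to several Arabidopsis genes: ",
         paste(utils::head(at_conflict$syntelog_group, 3), collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(tbl, .data$group_id, .data$subgenome)
}

# Layer helpers -----------------------------------------------------------

get_lognorm <- function(ds, caller) {
  if (is.null(ds$lognorm)) {
    stop(caller, " requires the lognorm layer; run log_normalize() first",
         call. = FALSE)
  }
  ds$lognorm
}
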