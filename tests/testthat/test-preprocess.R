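# QC filtering, LogNormalize, composition, correlation, annotation.

make_qc_dataset <- function() {
  # three cells: 499 UMIs (too few), 500 over 250 genes (boundary, kept),
  # one with 12000 detected genes (too many)
  n_genes <- 12000
  m <- Matrix::sparseMatrix(
    i = c(1:499,
          500 + (1:250),
          1:n_genes),
    j = c(rep(1, 499), rep(2, 250), rep(3, n_genes)),
    x = c(rep(1, 499), rep(2, 250), rep(1, n_genes)),
    dims = c(n_genes, 3),
    dimnames = list(sprintf("g%05d", 1:n_genes), c("low", "edge", "wide")))
  cells <- tibble::tibble(barcode = c("low", "edge", "wide"),
                          sample_id = "L1", tissue = "leaf",
                          condition = "control",
                          cluster_id = NA_integer_,
                          cell_type = NA_character_)
  genes <- tibble::tibble(gene_id = rownames(m), subgenome = "UG",
                          syntelog_group = NA_character_,
                          at_ortholog = NA_character_,
                          family = NA_character_)
  sc_dataset(m, cells, genes)
}

test_that("QC removes out-of-bounds cells with reasons, keeps boundaries,
           and is idempotent", {
  ds <- make_qc_dataset()
  out <- qc_filter_cells(ds)
  rep <- qc_report(out)
  expect_setequal(colnames(out$counts), "edge")
  expect_equal(rep$reason[rep$barcode == "low"], "umi_low")
  expect_equal(rep$reason[rep$barcode == "wide"], "genes_high")
  expect_true(rep$kept[rep$barcode == "edge"])
  twice <- qc_filter_cells(out)
  expect_identical(as.matrix(twice$counts), as.matrix(out$counts))
  expect_true(all(qc_report(twice)$kept))
})

test_that("LogNormalize matches its closed form and preserves zeros and
           within-cell ranks", {
  counts <- Matrix::Matrix(matrix(c(2, 0, 2, 1, 3, 0), nrow = 3,
                                  dimnames = list(paste0("g", 1:3),
                                                  c("c1", "c2"))),
                           sparse = TRUE)
  cells <- tibble::tibble(barcode = c("c1", "c2"), sample_id = "s",
                          tissue = "leaf", condition = "control",
                          cluster_id = NA_integer_, cell_type = NA_character_)
  genes <- tibble::tibble(gene_id = paste0("g", 1:3), subgenome = "UG",
                          syntelog_group = NA_character_,
                          at_ortholog = NA_character_,
                          family = NA_character_)
  ds <- sc_dataset(counts, cells, genes)
  ds10 <- log_normalize(ds, scale = 10)
  # count 2, cell total 4, scale 10 -> ln(1 + 5)
  expect_equal(ds10$lognorm["g1", "c1"], log(6), tolerance = 1e-12)
  expect_equal(ds10$lognorm["g2", "c1"], 0)
  # rank order within each cell preserved
  ds2 <- log_normalize(ds)
  expect_equal(order(as.numeric(ds2$lognorm[, "c2"])),
               order(as.numeric(counts[, "c2"])))
  # closed-form inverse: expm1 then per-cell rescale recovers proportions
  raw_prop <- as.numeric(counts[, "c1"]) / sum(counts[, "c1"])
  rec <- expm1(as.numeric(ds2$lognorm[, "c1"]))
  expect_equal(rec / sum(rec), raw_prop, tolerance = 1e-12)
})

test_that("cells with zero totals stop normalization with their barcode", {
  ds <- toy_dataset()
  ds$counts[, "c2"] <- 0
  expect_error(log_normalize(ds), "c2")
})

test_that("composition normalizes each sample to the scale and flags
           enrichment from the Fisher test", {
  # cluster 0: shoot 90 / leaf 10; cluster 1: shoot 910 / leaf 990
  cells <- tibble::tibble(
    barcode = sprintf("b%04d", 1:2000),
    sample_id = rep(c("S1", "L1"), each = 1000),
    tissue = rep(c("shoot", "leaf"), each = 1000),
    condition = "control",
    cluster_id = c(rep(0L, 90), rep(1L, 910), rep(0L, 10), rep(1L, 990)),
    cell_type = NA_character_)
  m <- Matrix::sparseMatrix(i = rep(1, 2000), j = 1:2000, x = 1,
                            dims = c(2, 2000),
                            dimnames = list(c("g1", "g2"), cells$barcode))
  genes <- tibble::tibble(gene_id = c("g1", "g2"), subgenome = "UG",
                          syntelog_group = NA_character_,
                          at_ortholog = NA_character_,
                          family = NA_character_)
  ds <- sc_dataset(m, cells, genes)
  comp <- cluster_composition(ds)
  sums <- tapply(comp$n_normalized, comp$sample_id, sum)
  expect_true(all(abs(sums - 10000) < 0.5))
  row0 <- comp[comp$cluster_id == 0 & comp$sample_id == "S1", ]
  expect_equal(row0$odds_ratio, (90 * 990) / (910 * 10), tolerance = 1e-12)
  expect_equal(row0$enrichment, "shoot")
  expect_true(all(comp$bh_q >= comp$fisher_p - 1e-12))
  # balanced cluster: p = 1
  cells$cluster_id <- rep(c(0L, 1L), 1000)
  ds_bal <- sc_dataset(m, cells, genes)
  comp_bal <- cluster_composition(ds_bal)
  expect_equal(unique(comp_bal$fisher_p), 1)
  expect_true(all(comp_bal$enrichment == "none"))
})

test_that("single-tissue composition returns counts without test columns", {
  ds <- toy_dataset()
  ds <- filter_cells(ds, tissue == "leaf")
  comp <- cluster_composition(ds)
  expect_true(all(is.na(comp$fisher_p)))
  expect_equal(sum(comp$n_normalized), 10000)
})

test_that("cluster correlation is symmetric, unit-diagonal, and 1 for
           duplicated profiles", {
  sim <- cached_sim("tiny3", tiny_config(seed = 3L))
  ds <- log_normalize(sim$dataset)
  cc <- cluster_correlation(ds)
  expect_equal(cc, t(cc), tolerance = 1e-12)
  expect_equal(unname(diag(cc)), rep(1, nrow(cc)), tolerance = 1e-12)
  # duplicate a cluster: split cluster 0 cells into two fake clusters with
  # identical profiles by duplicating the dataset columns
  ds2 <- ds
  idx <- which(ds2$cells$cluster_id == 0L)
  half <- idx[seq_len(floor(length(idx) / 2))]
  ds2$cells$cluster_id[half] <- 99L
  cc2 <- cluster_correlation(ds2)
  expect_gt(cc2["0", "99"], 0.95)
})

test_that("within-cell-type cluster pairs correlate more strongly than
           across-type pairs", {
  sim <- cached_sim("tiny3", tiny_config(seed = 3L))
  ds <- log_normalize(sim$dataset)
  # split mesophyll (cluster 0) into two clusters of the same type
  idx <- which(ds$cells$cluster_id == 0L)
  ds$cells$cluster_id[idx[seq_len(floor(length(idx) / 2))]] <- 10L
  cc <- cluster_correlation(ds)
  within <- cc["0", "10"]
  across <- max(cc["0", setdiff(colnames(cc), c("0", "10"))])
  expect_gt(within, across)
})

test_that("annotation recovers planted cell types, reports unknowns and
           breaks ties lexicographically", {
  env <- default_sim()
  ds <- env$dataset
  truth <- env$truth
  marker_table <- tibble::tibble(
    cell_type = rep(names(truth$marker_genes), lengths(truth$marker_genes)),
    gene_id = unlist(truth$marker_genes, use.names = FALSE))
  ann <- annotate_clusters(ds, marker_table)
  types <- sim_config()$cell_types
  expected <- tibble::tibble(cluster_id = seq_along(types) - 1L,
                             cell_type = types)
  got <- ann$assignments[match(expected$cluster_id,
                               ann$assignments$cluster_id), ]
  expect_equal(got$cell_type, expected$cell_type)
  expect_true(all(ann$dotplot$frac_expressing >= 0 &
                    ann$dotplot$frac_expressing <= 1))
  ds2 <- set_cell_types(ds, ann)
  expect_equal(ds2$cells$cell_type, ds$cells$cell_type)

  # absent marker genes are skipped with a warning
  expect_warning(annotate_clusters(ds, dplyr::bind_rows(
    marker_table, tibble::tibble(cell_type = "guard", gene_id = "absent"))),
    "absent")

  # a marker set identical for two types produces a tie broken by name
  two <- dplyr::filter(marker_table, cell_type == "guard")
  tie_table <- dplyr::bind_rows(two,
                                dplyr::mutate(two, cell_type = "aaa_type"))
  ann_tie <- annotate_clusters(ds, tie_table)
  guard_row <- ann_tie$assignments[ann_tie$assignments$cluster_id == 2L, ]
  expect_true(guard_row$tie)
  expect_equal(guard_row$cell_type, "aaa_type")
})
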