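# Expressed-gene sets, subgenome proportions, copy classes, dominance.

# one cell type, equal per-cell totals; counts: named list gene -> per-cell
# count vector (length n)
one_type_dataset <- function(counts, subgenome, syntelog_group = NULL,
                             cell_type = "mesophyll") {
  n <- length(counts[[1]])
  m <- do.call(rbind, counts)
  m <- Matrix::Matrix(m, sparse = TRUE)
  colnames(m) <- sprintf("c%03d", seq_len(n))
  cells <- tibble::tibble(barcode = colnames(m), sample_id = "L1",
                          tissue = "leaf", condition = "control",
                          cluster_id = 0L, cell_type = cell_type)
  genes <- tibble::tibble(
    gene_id = names(counts),
    subgenome = subgenome,
    syntelog_group = if (is.null(syntelog_group)) NA_character_
                     else syntelog_group,
    at_ortholog = ifelse(subgenome == "UG", NA_character_,
                         paste0("AT", seq_along(counts))),
    family = NA_character_)
  if (!is.null(syntelog_group)) {
    genes$at_ortholog <- ifelse(is.na(genes$syntelog_group), NA_character_,
                                paste0("AT_", genes$syntelog_group))
  }
  log_normalize(sc_dataset(m, cells, genes))
}

test_that("expressed-gene call uses an inclusive 5% boundary", {
  n <- 100
  ds <- one_type_dataset(
    list(g4 = c(rep(1, 4), rep(0, 96)),
         g5 = c(rep(1, 5), rep(0, 95)),
         all = rep(1, 100)),
    subgenome = c("UG", "UG", "UG"))
  ex <- expressed_genes(ds, "mesophyll")
  expect_false("g4" %in% ex)
  expect_true("g5" %in% ex)
  expect_true("all" %in% ex)
  expect_error(expressed_genes(ds, "guard"), "guard")
})

test_that("expressed set grows monotonically as the threshold drops", {
  sim <- cached_sim("tiny3", tiny_config(seed = 3L))
  ds <- log_normalize(sim$dataset)
  strict <- ds
  strict$thresholds <- sc_thresholds(expressed_cell_frac = 0.2)
  loose <- ds
  loose$thresholds <- sc_thresholds(expressed_cell_frac = 0.02)
  e_strict <- expressed_genes(strict, "guard")
  e_loose <- expressed_genes(loose, "guard")
  expect_true(all(e_strict %in% e_loose))
})

test_that("subgenome proportions tabulate the toy example and sum to one", {
  ds <- one_type_dataset(
    list(a = rep(1, 20), b = rep(2, 20), c = rep(1, 20), d = rep(3, 20)),
    subgenome = c("LF", "LF", "MF1", "UG"),
    syntelog_group = c("s1", "s2", "s3", NA))
  props <- subgenome_proportions(ds)
  expect_equal(props$proportion[props$subgenome == "LF"], 0.5)
  expect_equal(props$proportion[props$subgenome == "MF1"], 0.25)
  expect_equal(props$proportion[props$subgenome == "MF2"], 0)
  expect_equal(props$proportion[props$subgenome == "UG"], 0.25)
  expect_equal(sum(props$proportion), 1)
  # all-UG dataset
  ds_ug <- one_type_dataset(list(u1 = rep(1, 10), u2 = rep(2, 10)),
                            subgenome = c("UG", "UG"))
  p_ug <- subgenome_proportions(ds_ug)
  expect_equal(p_ug$proportion[p_ug$subgenome == "UG"], 1)
  expect_true(all(p_ug$proportion[p_ug$subgenome != "UG"] == 0))
})

test_that("copy-class expressed fractions count per class, with NA for empty
           classes", {
  # 1:2 class holds 4 genes (2 groups); 3 of them expressed
  ds <- one_type_dataset(
    list(a1 = rep(1, 100), a2 = rep(1, 100),
         b1 = rep(1, 100), b2 = c(1, rep(0, 99)),
         u = rep(1, 100)),
    subgenome = c("LF", "MF1", "LF", "MF2", "UG"),
    syntelog_group = c("s1", "s1", "s2", "s2", NA))
  cc <- copy_class_expression(ds)
  expect_equal(cc$fraction[cc$copy_class == "1:2"], 0.75)
  expect_true(is.na(cc$fraction[cc$copy_class == "1:1"]))
  expect_true(is.na(cc$fraction[cc$copy_class == "1:3"]))
  expect_equal(cc$fraction[cc$copy_class == "UG"], 1)
})

test_that("UG expressed fraction sits below every syntenic class on
           simulated data", {
  sim <- cached_sim("tiny3", tiny_config(seed = 3L))
  ds <- log_normalize(sim$dataset)
  cc <- copy_class_expression(ds)
  for (t in unique(cc$cell_type)) {
    sub <- cc[cc$cell_type == t, ]
    ug <- sub$fraction[sub$copy_class == "UG"]
    syntenic <- sub$fraction[sub$copy_class != "UG"]
    expect_true(all(ug < syntenic))
  }
})

test_that("dominance needs a clear winner: fold-change gate, p gate and the
           5% expression gate all bind", {
  n <- 100
  filler <- rep(91, n)
  # A twice B: dominant
  ds_dom <- one_type_dataset(
    list(A = rep(8, n), B = rep(4, n), filler = filler - 4),
    subgenome = c("LF", "MF1", "UG"),
    syntelog_group = c("s1", "s1", NA))
  call_dom <- dominance_call(ds_dom, "s1", "mesophyll")
  expect_equal(call_dom$call$dominant_subgenome, "LF")
  # identical copies: p = 1, none
  ds_eq <- one_type_dataset(
    list(A = rep(4, n), B = rep(4, n), filler = filler),
    subgenome = c("LF", "MF1", "UG"),
    syntelog_group = c("s1", "s1", NA))
  call_eq <- dominance_call(ds_eq, "s1", "mesophyll")
  expect_true(is.na(call_eq$call$dominant_subgenome))
  expect_equal(call_eq$pairs$p, 1)
  # log2fc ~ 0.32 < 0.36: effect-size gate blocks despite tiny p
  ds_small <- one_type_dataset(
    list(A = rep(5, n), B = rep(4, n), filler = filler - 1),
    subgenome = c("LF", "MF1", "UG"),
    syntelog_group = c("s1", "s1", NA))
  call_small <- dominance_call(ds_small, "s1", "mesophyll")
  expect_lt(abs(call_small$pairs$log2fc), 0.36)
  expect_lt(call_small$pairs$p, 0.001)
  expect_true(is.na(call_small$call$dominant_subgenome))
  # candidate below the 5% expression gate cannot win
  ds_rare <- one_type_dataset(
    list(A = c(rep(400, 3), rep(0, n - 3)), B = rep(1, n),
         filler = rep(100, n)),
    subgenome = c("LF", "MF1", "UG"),
    syntelog_group = c("s1", "s1", NA))
  call_rare <- dominance_call(ds_rare, "s1", "mesophyll")
  expect_true(is.na(call_rare$call$dominant_subgenome))
})

test_that("single-copy groups are rejected", {
  ds <- one_type_dataset(
    list(A = rep(2, 10), B = rep(2, 10)),
    subgenome = c("LF", "MF1"),
    syntelog_group = c("s1", "s2"))
  expect_error(dominance_call(ds, "s1", "mesophyll"), "single copy")
  expect_error(dominance_calls(ds, groups = "s2"), "single-copy")
})

test_that("dominance is exclusive and calls agree between the batch and
           single-group interfaces", {
  env <- default_sim()
  ctrl <- filter_cells(env$dataset, condition == "control")
  calls <- dominance_calls(ctrl, cell_types = "guard")
  expect_false(anyDuplicated(paste(calls$group_id, calls$cell_type)) > 0)
  some <- calls[!is.na(calls$dominant_gene), ][1:3, ]
  for (i in seq_len(nrow(some))) {
    single <- dominance_call(ctrl, some$group_id[i], "guard")
    expect_equal(single$call$dominant_gene, some$dominant_gene[i])
  }
})

test_that("dominance counts tabulate winners per subgenome with zeros kept", {
  calls <- tibble::tibble(
    group_id = c("s1", "s2", "s3"),
    cell_type = "mesophyll",
    copy_class = 2L,
    dominant_gene = c("a", "b", "c"),
    dominant_subgenome = c("LF", "LF", "MF1"))
  dc <- dominance_counts(calls)
  expect_equal(dc$n[dc$subgenome == "LF"], 2L)
  expect_equal(dc$n[dc$subgenome == "MF1"], 1L)
  expect_equal(dc$n[dc$subgenome == "MF2"], 0L)
  none <- dplyr::mutate(calls, dominant_gene = NA_character_,
                        dominant_subgenome = NA_character_)
  expect_true(all(dominance_counts(none)$n == 0))
})
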