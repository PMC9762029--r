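# Heat-stress DE, partitioning, markers, opposite patterns, UMI shift,
# reference genes, subgenome counts, family summaries.

toy_heat_table <- function() {
  tibble::tibble(
    cell_type = c("mesophyll", "mesophyll", "epidermal", "epidermal",
                  "guard", "vascular", "mesophyll"),
    gene_id = c("a", "b", "b", "c", "g", "w", "w"),
    log2fc = c(1, 0.8, 0.9, 1.2, -0.7, 0.9, -0.8),
    p = 0.001, q = 0.01,
    pct_heat = 0.5, pct_control = 0.5, pct_type = 0.5,
    direction = c("up", "up", "up", "up", "down", "up", "down"))
}

test_that("every reported DEG satisfies the fold-change, p and detection
           gates", {
  env <- default_sim()
  ds <- env$dataset
  th <- ds$thresholds
  degs <- condition_degs(ds, "mesophyll")
  expect_gt(nrow(degs), 0)
  expect_true(all(abs(degs$log2fc) >= th$heat_log2fc))
  expect_true(all(degs$p < th$heat_p))
  expect_true(all(degs$pct_type > th$heat_target_frac))
  expect_true(all((degs$log2fc > 0) == (degs$direction == "up")))
  expect_error(condition_degs(filter_cells(ds, condition == "control"),
                              "mesophyll"), ">= 3 cells")
})

test_that("DEG subset partition performs exact set algebra", {
  ht <- tibble::tibble(
    cell_type = c("mesophyll", "mesophyll", "guard", "guard"),
    gene_id = c("a", "b", "b", "c"),
    log2fc = 1, p = 0.01, q = 0.05,
    pct_heat = 0.5, pct_control = 0.5, pct_type = 0.5,
    direction = "up")
  part <- deg_partition(ht)
  expect_setequal(part$shared_all$up, "b")
  expect_setequal(part$specific$up$mesophyll, "a")
  expect_setequal(part$specific$up$guard, "c")
  expect_length(part$shared_all$down, 0)
  # disjoint up-sets give an empty shared set
  ht2 <- dplyr::mutate(ht, gene_id = c("a", "b", "c", "d"))
  expect_length(deg_partition(ht2)$shared_all$up, 0)
  expect_error(deg_partition(ht[ht$cell_type == "guard", ]), ">= 2")
})

test_that("partition subsets are disjoint and cover the per-type DEG union", {
  env <- default_sim()
  ht <- heat_deg_table(env$dataset)
  part <- deg_partition(ht)
  for (d in c("up", "down")) {
    m <- part$membership[part$membership$direction == d, ]
    expect_false(anyDuplicated(m$gene_id) > 0)   # subsets partition
    expect_setequal(m$gene_id, unique(ht$gene_id[ht$direction == d]))
  }
})

test_that("heat markers are DEGs of exactly one cell type", {
  part <- deg_partition(toy_heat_table())
  hm <- heat_marker_genes(part)
  expect_true("a" %in% hm$gene_id[hm$cell_type == "mesophyll"])
  expect_true("g" %in% hm$gene_id[hm$cell_type == "guard"])
  expect_true("c" %in% hm$gene_id[hm$cell_type == "epidermal"])
  expect_false("b" %in% hm$gene_id)   # two types, same direction
  expect_false("w" %in% hm$gene_id)   # two types, opposite directions
  # markers plus multi-type genes cover all DEGs; marker sets are disjoint
  env <- default_sim()
  ht <- heat_deg_table(env$dataset)
  part2 <- deg_partition(ht)
  hm2 <- heat_marker_genes(part2)
  expect_false(anyDuplicated(hm2$gene_id) > 0)
  expect_true(all(hm2$gene_id %in% ht$gene_id))
})

test_that("opposite-pattern genes need both directions in different types", {
  op <- opposite_pattern_genes(toy_heat_table())
  expect_setequal(unique(op$gene_id), "w")
  expect_setequal(op$direction[op$gene_id == "w"], c("up", "down"))
  # up in two types only is not opposite
  expect_false("b" %in% op$gene_id)
})

test_that("UMI shift test flags the planted depth drop except in
           proliferating cells and stays quiet on identical data", {
  env <- default_sim()
  shift <- umi_shift_test(env$dataset)
  drop_types <- shift$cell_type[shift$p < 0.01 &
                                  shift$median_heat < shift$median_control]
  expect_setequal(drop_types,
                  c("mesophyll", "epidermal", "guard", "vascular"))
  expect_gt(shift$p[shift$cell_type == "proliferating"], 0.05)
  # identical distributions: no call
  ctrl <- filter_cells(env$dataset, condition == "control")
  half <- ctrl
  flip <- seq_len(nrow(half$cells)) %% 2 == 0
  half$cells$condition[flip] <- "heat"
  null_shift <- umi_shift_test(half, "mesophyll")
  expect_gt(null_shift$p, 0.05)
})

test_that("reference-gene stability reports pass, fail and untestable, with
           vacuous pass on an empty list", {
  env <- default_sim()
  ht <- heat_deg_table(env$dataset)
  genes <- env$dataset$genes$gene_id
  stable <- setdiff(genes, ht$gene_id)[1:3]
  planted_up <- intersect(env$truth$shared_up, ht$gene_id)[1]
  chk <- reference_gene_check(ht, c(stable, planted_up, "not_a_gene"), genes)
  expect_true(all(chk$status[chk$gene_id %in% stable] == "pass"))
  expect_true(any(chk$status[chk$gene_id == planted_up] == "fail"))
  expect_true(all(chk$status[chk$gene_id == "not_a_gene"] == "untestable"))
  expect_false(glance(chk)$overall_pass)
  chk2 <- reference_gene_check(ht, stable, genes)
  expect_true(glance(chk2)$overall_pass)
  expect_warning(empty <- reference_gene_check(ht, character(0), genes),
                 "vacuous")
  expect_true(glance(empty)$overall_pass)
})

test_that("subgenome DEG counts tabulate direction splits with zeros", {
  ht <- toy_heat_table()[1:3, ]   # a(meso up), b(meso up), b(epi up)
  genes <- tibble::tibble(gene_id = c("a", "b", "c", "g", "w"),
                          subgenome = c("LF", "LF", "MF2", "MF1", "UG"))
  counts <- subgenome_deg_counts(ht, genes)
  meso_lf <- counts[counts$cell_type == "mesophyll" &
                      counts$subgenome == "LF", ]
  expect_equal(meso_lf$n_up, 2L)
  expect_equal(meso_lf$n_total, 2L)
  expect_equal(counts$n_total[counts$cell_type == "mesophyll" &
                                counts$subgenome == "MF2"], 0L)
  expect_equal(nrow(subgenome_deg_counts(ht[0, ], genes)), 0)
})

test_that("family summaries transcribe the DEG table with ns elsewhere and
           reject unknown tags", {
  genes <- tibble::tibble(
    gene_id = c("h1", "h2", "h3", "x"),
    subgenome = c("LF", "MF1", "MF2", "UG"),
    syntelog_group = c("s1", "s1", "s1", NA),
    family = c("HSP", "HSP", "HSP", NA))
  ht <- tibble::tibble(
    cell_type = c("vascular", "vascular"),
    gene_id = c("h1", "h3"),
    log2fc = c(-1, 1), p = 0.001, q = 0.01,
    pct_heat = 0.5, pct_control = 0.5, pct_type = 0.5,
    direction = c("down", "up"))
  fam <- family_summary(ht, genes, "HSP",
                        cell_types = c("mesophyll", "vascular"))
  expect_equal(
    fam$status[fam$gene_id == "h1" & fam$cell_type == "vascular"], "down")
  expect_equal(
    fam$status[fam$gene_id == "h3" & fam$cell_type == "vascular"], "up")
  expect_true(all(fam$status[fam$cell_type == "mesophyll"] == "ns"))
  expect_true(all(fam$status[fam$gene_id == "h2"] == "ns"))
  expect_error(family_summary(ht, genes, "NLR"), "HSP")
})
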