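# Seeded generator of datasets with the statistical structure the analysis
# assumes (triplicated-genome leaf scRNA-seq with a heat arm), plus ground
# truth for recovery benchmarks.

#' Simulation configuration
#'
#' Parameters of the generative model in [simulate_dataset()]. Defaults model
#' the leaf heat-stress experiment: five leaf cell types, 200 cells per type
#' per condition, a gene catalog of 300 one-to-one, 300 one-to-two and 200
#' one-to-three syntelog groups with LF-biased retention plus 400 ungrouped
#' (UG) genes that are mostly silenced, LF-biased planted dominance, 30
#' markers per cell type, and heat-response sets of 150 shared-up / 92
#' shared-down genes, 50 type-specific genes per type and 20 opposite-pattern
#' genes. Library sizes are log-normal around 5,000 UMIs, clipped to
#' \[500, 50000\], with heat shrinking every type's depth to 0.8x except
#' proliferating cells; counts are negative binomial with dispersion
#' `nb_dispersion` (Poisson at 0).
#'
#' @param seed Integer seed consumed by [simulate_dataset()].
#' @param cell_types Ordered cell-type labels.
#' @param cells_per_type_per_condition Cells per (type, condition) block.
#' @param n11,n12,n13 Numbers of 1:1, 1:2 and 1:3 syntelog groups.
#' @param n_ug Number of ungrouped genes.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline of per-group
#'   expression rates, on the expected-counts-per-10k scale.
#' @param copy_jitter_log2_sd Per-copy log2-normal jitter around the group
#'   baseline. The default 0 makes unplanted homoeologs exchangeable, so the
#'   planted dominant copies are the only within-group asymmetries and the
#'   ground truth is a complete benchmark; positive values add baseline
#'   divergence between homoeologs (more realistic, but dominance calls on
#'   divergent unplanted groups then count against ground truth).
#' @param ug_silent_fraction,ug_silent_factor Fraction of UG genes silenced
#'   and the multiplicative rate factor applied to them.
#' @param retention_pair_probs Probabilities of the subgenome pair retained in
#'   1:2 groups (names "LF+MF1", "LF+MF2", "MF1+MF2"); must sum to 1.
#' @param retention_single_probs Subgenome of the single retained copy in 1:1
#'   groups (names "LF", "MF1", "MF2"); must sum to 1.
#' @param f_dom Fraction of multi-copy groups with a planted dominant copy.
#' @param dom_subgenome_probs Subgenome preference of the planted dominant
#'   copy (renormalized over the subgenomes present in each group).
#' @param delta_dom Dominance effect (log2 units).
#' @param m_markers_per_type,beta_marker Planted markers per type and their
#'   within-type log2 effect.
#' @param n_shared_up,n_shared_down Heat genes up-/down-regulated in all
#'   types.
#' @param n_specific_per_type Heat genes regulated in exactly one type.
#' @param specific_up_prob Probability a type-specific heat gene is
#'   up-regulated.
#' @param n_opposite Heat genes with per-type signs mixing up and down.
#' @param gamma_heat Heat effect (log2 units).
#' @param heat_umi_factor Named per-type library-depth factor under heat.
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size target.
#' @param libsize_min,libsize_max Clip bounds on the library target.
#' @param nb_dispersion Negative-binomial dispersion phi in
#'   `var = mu + phi * mu^2`; 0 gives Poisson counts.
#' @param eligible_min_rate Minimum baseline rate (per 10k) for genes eligible
#'   to carry planted marker/heat effects; effects planted in near-silent
#'   genes would be undetectable under the expressed-fraction gates.
#' @param conditions Conditions to simulate (subset of "control", "heat").
#'
#' @return A list of class `sc_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       cell_types = c("mesophyll", "epidermal", "guard",
                                      "vascular", "proliferating"),
                       cells_per_type_per_condition = 200L,
                       n11 = 300L, n12 = 300L, n13 = 200L, n_ug = 400L,
                       baseline_log_mean = log(0.5), baseline_log_sd = 1,
                       copy_jitter_log2_sd = 0,
                       ug_silent_fraction = 0.8, ug_silent_factor = 0.01,
                       retention_pair_probs = c("LF+MF1" = 0.45,
                                                "LF+MF2" = 0.35,
                                                "MF1+MF2" = 0.20),
                       retention_single_probs = c(LF = 0.5, MF1 = 0.3,
                                                  MF2 = 0.2),
                       f_dom = 0.3,
                       dom_subgenome_probs = c(LF = 0.6, MF1 = 0.25,
                                               MF2 = 0.15),
                       delta_dom = 1.0,
                       m_markers_per_type = 30L, beta_marker = 2.0,
                       n_shared_up = 150L, n_shared_down = 92L,
                       n_specific_per_type = 50L, specific_up_prob = 0.6,
                       n_opposite = 20L, gamma_heat = 1.0,
                       heat_umi_factor = NULL,
                       libsize_log_mean = log(5000), libsize_log_sd = 0.4,
                       libsize_min = 500, libsize_max = 50000,
                       nb_dispersion = 0.5,
                       eligible_min_rate = 0.35,
                       conditions = c("control", "heat")) {
  if (is.null(heat_umi_factor)) {
    heat_umi_factor <- stats::setNames(rep(0.8, length(cell_types)),
                                       cell_types)
    heat_umi_factor[cell_types == "proliferating"] <- 1.0
  }
  cfg <- list(
    seed = as.integer(seed), cell_types = cell_types,
    cells_per_type_per_condition = as.integer(cells_per_type_per_condition),
    n11 = as.integer(n11), n12 = as.integer(n12), n13 = as.integer(n13),
    n_ug = as.integer(n_ug),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    copy_jitter_log2_sd = copy_jitter_log2_sd,
    ug_silent_fraction = ug_silent_fraction,
    ug_silent_factor = ug_silent_factor,
    retention_pair_probs = retention_pair_probs,
    retention_single_probs = retention_single_probs,
    f_dom = f_dom, dom_subgenome_probs = dom_subgenome_probs,
    delta_dom = delta_dom,
    m_markers_per_type = as.integer(m_markers_per_type),
    beta_marker = beta_marker,
    n_shared_up = as.integer(n_shared_up),
    n_shared_down = as.integer(n_shared_down),
    n_specific_per_type = as.integer(n_specific_per_type),
    specific_up_prob = specific_up_prob,
    n_opposite = as.integer(n_opposite), gamma_heat = gamma_heat,
    heat_umi_factor = heat_umi_factor,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
    libsize_min = libsize_min, libsize_max = libsize_max,
    nb_dispersion = nb_dispersion,
    eligible_min_rate = eligible_min_rate,
    conditions = match.arg(conditions, c("control", "heat"),
                           several.ok = TRUE)
  )
  for (nm in c("retention_pair_probs", "retention_single_probs",
               "dom_subgenome_probs")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-12) {
      stop("`", nm, "` must sum to 1", call. = FALSE)
    }
    if (any(cfg[[nm]] < 0)) stop("`", nm, "` must be non-negative",
                                 call. = FALSE)
  }
  counts <- c(cfg$cells_per_type_per_condition, cfg$n11, cfg$n12, cfg$n13,
              cfg$n_ug, cfg$m_markers_per_type)
  if (any(counts <= 0)) stop("all size parameters must be positive",
                             call. = FALSE)
  effs <- c(cfg$delta_dom, cfg$beta_marker, cfg$gamma_heat)
  if (any(!is.finite(effs))) stop("effect sizes must be finite", call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (!all(cfg$cell_types %in% names(cfg$heat_umi_factor))) {
    stop("heat_umi_factor must name every cell type", call. = FALSE)
  }
  structure(cfg, class = "sc_sim_config")
}

# Draw counts for one (type, condition) block; lambda already includes all
# effect multipliers. Library targets are renormalized per cell so depth, not
# gene count, sets the totals.
draw_block <- function(lambda, n_cells, cfg, depth_factor) {
  L <- stats::rlnorm(n_cells, cfg$libsize_log_mean, cfg$libsize_log_sd) *
    depth_factor
  L <- pmin(pmax(L, cfg$libsize_min), cfg$libsize_max)
  mu <- outer(lambda / sum(lambda), L)
  n <- length(mu)
  if (cfg$nb_dispersion > 0) {
    counts <- stats::rnbinom(n, mu = as.vector(mu),
                             size = 1 / cfg$nb_dispersion)
  } else {
    counts <- stats::rpois(n, as.vector(mu))
  }
  matrix(counts, nrow = length(lambda))
}

#' Simulate a triplicated-genome single-cell dataset with ground truth
#'
#' Generative model, consuming a single RNG stream in this order:
#' (1) build the gene catalog from the syntelog-group counts, with subgenome
#' assignment by the retention probabilities, plus UG genes;
#' (2) draw one baseline rate per syntelog group (log-normal, per-10k scale),
#' shared by the group's copies up to a small per-copy log2 jitter, and
#' independently per UG gene, silencing a fraction of UG genes;
#' (3) plant a dominant copy (rate x `2^delta_dom`) in a fraction `f_dom` of
#' multi-copy groups, preferring the LF subgenome;
#' (4) plant `m_markers_per_type` markers per cell type (rate x
#' `2^beta_marker` in that type's cells only);
#' (5) plant heat-response sets (shared, type-specific, opposite-signed; rate
#' x `2^(+/- gamma_heat)` in heat cells of the affected types) and shrink heat
#' cells' library targets by `heat_umi_factor`;
#' (6) draw per-cell library sizes (clipped log-normal) and negative-binomial
#' counts with dispersion `nb_dispersion`.
#'
#' @param config An [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list with elements `dataset` (an [sc_dataset()] with raw counts,
#'   true `cell_type` labels and `cluster_id` set to the cell-type index) and
#'   `truth` (class `sc_ground_truth`): `marker_genes`, `dominant_copy`,
#'   `heat_up`, `heat_down` (per-type lists containing the shared sets) and
#'   `opposite_genes` (tibble of per-type signs).
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sc_sim_config"))
  cfg <- config
  set.seed(if (is.null(seed)) cfg$seed else as.integer(seed))
  types <- cfg$cell_types
  n_types <- length(types)

  ## (1) gene catalog
  n_groups <- cfg$n11 + cfg$n12 + cfg$n13
  group_ids <- sprintf("SG%05d", seq_len(n_groups))
  at_genes <- sprintf("AT%dG%05d", ((seq_len(n_groups) - 1) %% 5) + 1,
                      seq_len(n_groups) * 10)
  copy_class <- rep(c(1L, 2L, 3L), c(cfg$n11, cfg$n12, cfg$n13))
  members <- vector("list", n_groups)
  single <- sample(names(cfg$retention_single_probs), cfg$n11, replace = TRUE,
                   prob = cfg$retention_single_probs)
  pairs <- sample(names(cfg$retention_pair_probs), cfg$n12, replace = TRUE,
                  prob = cfg$retention_pair_probs)
  members[copy_class == 1L] <- as.list(single)
  members[copy_class == 2L] <- strsplit(pairs, "+", fixed = TRUE)
  members[copy_class == 3L] <- rep(list(c("LF", "MF1", "MF2")), cfg$n13)

  gene_tbl <- tibble(
    syntelog_group = rep(group_ids, lengths(members)),
    at_ortholog = rep(at_genes, lengths(members)),
    subgenome = unlist(members),
    copy_class = rep(copy_class, lengths(members))
  )
  gene_tbl <- dplyr::bind_rows(
    gene_tbl,
    tibble(syntelog_group = NA_character_, at_ortholog = NA_character_,
           subgenome = rep("UG", cfg$n_ug), copy_class = NA_integer_)
  )
  n_genes <- nrow(gene_tbl)
  gene_tbl$gene_id <- sprintf("BAA%02dg%05d",
                              ((seq_len(n_genes) - 1) %% 10) + 1,
                              seq_len(n_genes) * 10)
  gene_tbl$family <- NA_character_

  ## (2) baseline rates
  group_rate <- stats::setNames(
    stats::rlnorm(n_groups, cfg$baseline_log_mean, cfg$baseline_log_sd),
    group_ids)
  jitter <- 2^stats::rnorm(n_genes, 0, cfg$copy_jitter_log2_sd)
  lambda <- ifelse(is.na(gene_tbl$syntelog_group),
                   NA_real_, group_rate[gene_tbl$syntelog_group]) * jitter
  is_ug <- gene_tbl$subgenome == "UG"
  lambda[is_ug] <- stats::rlnorm(sum(is_ug), cfg$baseline_log_mean,
                                 cfg$baseline_log_sd) * jitter[is_ug]
  silent <- is_ug & stats::runif(n_genes) < cfg$ug_silent_fraction
  lambda[silent] <- lambda[silent] * cfg$ug_silent_factor

  ## (3) planted dominance
  multi_groups <- group_ids[copy_class >= 2L]
  n_dom <- round(cfg$f_dom * length(multi_groups))
  dom_groups <- sample(multi_groups, n_dom)
  dominant <- character(0)
  if (n_dom > 0) {
    dominant <- vapply(dom_groups, function(g) {
      memb <- gene_tbl$gene_id[!is.na(gene_tbl$syntelog_group) &
                                 gene_tbl$syntelog_group == g]
      sg <- gene_tbl$subgenome[match(memb, gene_tbl$gene_id)]
      w <- cfg$dom_subgenome_probs[sg]
      memb[sample.int(length(memb), 1, prob = w / sum(w))]
    }, character(1))
    idx <- match(dominant, gene_tbl$gene_id)
    lambda[idx] <- lambda[idx] * 2^cfg$delta_dom
  }
  dominant_copy <- tibble(
    group_id = dom_groups,
    gene_id = unname(dominant),
    subgenome = gene_tbl$subgenome[match(dominant, gene_tbl$gene_id)]
  )

  ## (4) planted markers
  ## Markers are planted in single-copy (1:1) or UG genes only: a marker
  ## effect on one homoeolog of a multi-copy group would be genuine cell-type
  ## dominance that the dominance ground truth does not record.
  eligible <- gene_tbl$gene_id[lambda >= cfg$eligible_min_rate &
                                 !(gene_tbl$gene_id %in% dominant)]
  single_copy <- gene_tbl$gene_id[is.na(gene_tbl$copy_class) |
                                    gene_tbl$copy_class == 1L]
  marker_pool <- intersect(eligible, single_copy)
  need_markers <- n_types * cfg$m_markers_per_type
  need_heat <- cfg$n_shared_up + cfg$n_shared_down +
    n_types * cfg$n_specific_per_type + cfg$n_opposite
  if (length(marker_pool) < need_markers ||
      length(eligible) < need_markers + need_heat) {
    stop("planted marker/heat set sizes exceed the eligible gene catalog (",
         length(marker_pool), " single-copy eligible for ", need_markers,
         " markers; ", length(eligible), " eligible for ",
         need_markers + need_heat, " total)", call. = FALSE)
  }
  marker_mult <- matrix(1, n_genes, n_types, dimnames = list(NULL, types))
  marker_genes <- list()
  for (t in types) {
    mk <- sample(marker_pool, cfg$m_markers_per_type)
    marker_pool <- setdiff(marker_pool, mk)
    marker_genes[[t]] <- mk
    marker_mult[match(mk, gene_tbl$gene_id), t] <- 2^cfg$beta_marker
  }
  pool <- setdiff(eligible, unlist(marker_genes))

  ## (5) heat-response sets
  shared_up <- sample(pool, cfg$n_shared_up); pool <- setdiff(pool, shared_up)
  shared_down <- sample(pool, cfg$n_shared_down)
  pool <- setdiff(pool, shared_down)
  specific <- list()
  specific_dir <- list()
  for (t in types) {
    sp <- sample(pool, cfg$n_specific_per_type)
    pool <- setdiff(pool, sp)
    specific[[t]] <- sp
    specific_dir[[t]] <- ifelse(stats::runif(length(sp)) < cfg$specific_up_prob,
                                "up", "down")
  }
  opp <- sample(pool, cfg$n_opposite)
  opp_sign <- matrix("down", cfg$n_opposite, n_types,
                     dimnames = list(opp, types))
  for (i in seq_along(opp)) {
    k_up <- sample.int(n_types - 1, 1)
    up_types <- sample(types, k_up)
    opp_sign[i, up_types] <- "up"
  }

  heat_mult <- matrix(1, n_genes, n_types, dimnames = list(NULL, types))
  heat_up <- list()
  heat_down <- list()
  for (t in types) {
    up_t <- c(shared_up, specific[[t]][specific_dir[[t]] == "up"],
              opp[opp_sign[, t] == "up"])
    down_t <- c(shared_down, specific[[t]][specific_dir[[t]] == "down"],
                opp[opp_sign[, t] == "down"])
    heat_mult[match(up_t, gene_tbl$gene_id), t] <- 2^cfg$gamma_heat
    heat_mult[match(down_t, gene_tbl$gene_id), t] <- 2^-cfg$gamma_heat
    heat_up[[t]] <- up_t
    heat_down[[t]] <- down_t
  }

  ## (6) counts, block by block in documented order
  n_cells_block <- cfg$cells_per_type_per_condition
  blocks <- list()
  meta <- list()
  cell_counter <- 0L
  for (t in types) {
    for (cond in cfg$conditions) {
      lam <- lambda * marker_mult[, t]
      depth <- 1
      if (cond == "heat") {
        lam <- lam * heat_mult[, t]
        depth <- cfg$heat_umi_factor[[t]]
      }
      blocks[[length(blocks) + 1L]] <- draw_block(lam, n_cells_block, cfg,
                                                  depth)
      bc <- sprintf("BC%06d", cell_counter + seq_len(n_cells_block))
      cell_counter <- cell_counter + n_cells_block
      meta[[length(meta) + 1L]] <- tibble(
        barcode = bc,
        sample_id = paste0("L1-", toupper(substr(cond, 1, 1))),
        tissue = "leaf",
        condition = cond,
        cluster_id = match(t, types) - 1L,
        cell_type = t
      )
    }
  }
  counts <- methods::as(do.call(cbind, blocks), "CsparseMatrix")
  cells <- dplyr::bind_rows(meta)
  dimnames(counts) <- list(gene_tbl$gene_id, cells$barcode)

  genes <- gene_tbl[, c("gene_id", "subgenome", "syntelog_group",
                        "at_ortholog", "family")]
  ds <- sc_dataset(counts, cells, genes)

  opposite_genes <- tibble(
    gene_id = rep(opp, n_types),
    cell_type = rep(types, each = cfg$n_opposite),
    direction = as.vector(opp_sign)
  )
  truth <- structure(
    list(
      marker_genes = marker_genes,
      dominant_copy = dominant_copy,
      heat_up = heat_up,
      heat_down = heat_down,
      shared_up = shared_up,
      shared_down = shared_down,
      specific_genes = purrr::map2(specific, specific_dir,
                                   ~tibble(gene_id = .x, direction = .y)),
      opposite_genes = opposite_genes,
      baseline_rate = stats::setNames(lambda, gene_tbl$gene_id)
    ),
    class = "sc_ground_truth"
  )
  list(dataset = ds, truth = truth)
}

#' @export
print.sc_ground_truth <- function(x, ...) {
  cat("<sc_ground_truth>\n")
  cat("  markers:", sum(lengths(x$marker_genes)), "genes across",
      length(x$marker_genes), "cell types\n")
  cat("  dominant copies:", nrow(x$dominant_copy), "groups\n")
  cat("  heat shared up/down:", length(x$shared_up), "/",
      length(x$shared_down), "\n")
  cat("  opposite-pattern genes:",
      length(unique(x$opposite_genes$gene_id)), "\n")
  invisible(x)
}
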