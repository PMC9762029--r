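# Shared fixtures: simulations are cached per (name) so several test files
# can reuse the same run without re-simulating.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, config) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, simulate_dataset(config), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# Default study conditions, normalized once.
default_sim <- function() {
  sim <- cached_sim("default", sim_config(seed = 101L))
  if (is.null(.sim_cache$default_norm)) {
    .sim_cache$default_norm <- log_normalize(qc_filter_cells(sim$dataset))
  }
  list(dataset = .sim_cache$default_norm, truth = sim$truth)
}

# Reduced-size config for fast unit tests; dots override the small defaults.
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, cells_per_type_per_condition = 60L,
               n11 = 80L, n12 = 80L, n13 = 50L, n_ug = 100L,
               m_markers_per_type = 8L,
               n_shared_up = 20L, n_shared_down = 12L,
               n_specific_per_type = 8L, n_opposite = 4L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Small hand-built dataset: 6 genes x 8 cells, two clusters, two tissues.
toy_dataset <- function() {
  counts <- Matrix::Matrix(rbind(
    g1 = c(5, 4, 6, 5, 0, 0, 1, 0),
    g2 = c(0, 1, 0, 0, 7, 6, 8, 7),
    g3 = c(2, 2, 2, 2, 2, 2, 2, 2),
    g4 = c(0, 0, 0, 0, 0, 0, 0, 1),
    g5 = c(3, 0, 2, 1, 0, 4, 0, 2),
    g6 = c(1, 1, 1, 1, 1, 1, 1, 1)
  ), sparse = TRUE)
  colnames(counts) <- paste0("c", 1:8)
  cells <- tibble::tibble(
    barcode = paste0("c", 1:8),
    sample_id = rep(c("S1", "L1"), each = 4),
    tissue = rep(c("shoot", "leaf"), each = 4),
    condition = "control",
    cluster_id = rep(c(0L, 1L), each = 4),
    cell_type = rep(c("meristem", "mesophyll"), each = 4)
  )
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    subgenome = c("LF", "MF1", "LF", "UG", "MF2", "MF1"),
    syntelog_group = c("sg1", "sg1", "sg2", NA, "sg2", "sg3"),
    at_ortholog = c("AT1", "AT1", "AT2", NA, "AT2", "AT3"),
    family = c("HSP", NA, NA, NA, "HSP", NA)
  )
  sc_dataset(counts, cells, genes)
}

# Independent sign-enumeration oracle for the paired signed-rank test.
signed_rank_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Textbook BH step-up, written independently of p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}
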