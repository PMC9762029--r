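#' Analysis thresholds
#'
#' Bundle of the numeric cutoffs used throughout the pipeline. Defaults follow
#' the published leaf/shoot single-cell study design: cells are kept when their
#' UMI total lies in \[500, 50000\] and their detected-gene count in
#' \[200, 10000\]; expression is log-normalized to 10,000 counts per cell;
#' cluster-enriched genes require a log2 fold change above 0.36 (a 1.28-fold
#' change), expression in at least 25% of cluster cells and BH q <= 0.01;
#' novel cell-type markers require log2FC > 0.5 and raw p <= 0.01 with the
#' 25%/<25% target/other-type fraction rule; a gene counts as expressed in a
#' cell type when detected in at least 5% of its cells; subgenome dominance and
#' heat-stress DE both use |log2FC| >= 0.36 with p <= 0.05 (heat DEGs
#' additionally require detection in more than 25% of the type's cells).
#'
#' @param qc_umi_min,qc_umi_max Inclusive per-cell UMI-total bounds.
#' @param qc_genes_min,qc_genes_max Inclusive per-cell detected-gene bounds.
#' @param lognorm_scale Per-cell scaling target for LogNormalize.
#' @param cluster_enriched_min_frac,cluster_enriched_log2fc,cluster_enriched_q
#'   Cluster-enriched gene rules (fraction in cluster, log2FC, BH q).
#' @param marker_log2fc,marker_p,marker_target_frac,marker_other_frac
#'   Cell-type marker rules.
#' @param expressed_cell_frac Fraction of a type's cells for the expressed-gene
#'   call.
#' @param dominance_log2fc,dominance_p Subgenome-dominance pairwise rules.
#' @param heat_log2fc,heat_p,heat_target_frac Heat-stress DEG rules.
#' @param composition_scale Per-sample cell-count normalization target.
#'
#' @return A list of class `sc_thresholds`.
#' @export
#' @examples
#' th <- sc_thresholds()
#' th$heat_log2fc
sc_thresholds <- function(qc_umi_min = 500, qc_umi_max = 50000,
                          qc_genes_min = 200, qc_genes_max = 10000,
                          lognorm_scale = 10000,
                          cluster_enriched_min_frac = 0.25,
                          cluster_enriched_log2fc = 0.36,
                          cluster_enriched_q = 0.01,
                          marker_log2fc = 0.5, marker_p = 0.01,
                          marker_target_frac = 0.25, marker_other_frac = 0.25,
                          expressed_cell_frac = 0.05,
                          dominance_log2fc = 0.36, dominance_p = 0.05,
                          heat_log2fc = 0.36, heat_p = 0.05,
                          heat_target_frac = 0.25,
                          composition_scale = 10000) {
  th <- list(
    qc_umi_min = qc_umi_min, qc_umi_max = qc_umi_max,
    qc_genes_min = qc_genes_min, qc_genes_max = qc_genes_max,
    lognorm_scale = lognorm_scale,
    cluster_enriched_min_frac = cluster_enriched_min_frac,
    cluster_enriched_log2fc = cluster_enriched_log2fc,
    cluster_enriched_q = cluster_enriched_q,
    marker_log2fc = marker_log2fc, marker_p = marker_p,
    marker_target_frac = marker_target_frac,
    marker_other_frac = marker_other_frac,
    expressed_cell_frac = expressed_cell_frac,
    dominance_log2fc = dominance_log2fc, dominance_p = dominance_p,
    heat_log2fc = heat_log2fc, heat_p = heat_p,
    heat_target_frac = heat_target_frac,
    composition_scale = composition_scale
  )
  fracs <- c("cluster_enriched_min_frac", "marker_target_frac",
             "marker_other_frac", "expressed_cell_frac", "heat_target_frac")
  ps <- c("cluster_enriched_q", "marker_p", "dominance_p", "heat_p")
  for (f in fracs) {
    if (!is.numeric(th[[f]]) || th[[f]] <= 0 || th[[f]] >= 1) {
      stop("threshold `", f, "` must lie in (0, 1)", call. = FALSE)
    }
  }
  for (p in ps) {
    if (!is.numeric(th[[p]]) || th[[p]] <= 0 || th[[p]] >= 1) {
      stop("threshold `", p, "` must lie in (0, 1)", call. = FALSE)
    }
  }
  if (th$qc_umi_min >= th$qc_umi_max) {
    stop("qc_umi_min must be smaller than qc_umi_max", call. = FALSE)
  }
  if (th$qc_genes_min >= th$qc_genes_max) {
    stop("qc_genes_min must be smaller than qc_genes_max", call. = FALSE)
  }
  if (th$lognorm_scale <= 0 || th$composition_scale <= 0) {
    stop("scales must be positive", call. = FALSE)
  }
  structure(th, class = "sc_thresholds")
}

#' @export
print.sc_thresholds <- function(x, ...) {
  cat("<sc_thresholds>\n")
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals)), " = ", vals, collapse = "\n"), "\n")
  invisible(x)
}
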