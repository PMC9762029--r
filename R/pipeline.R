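# End-to-end pipeline with a machine-readable run report.

pipeline_steps <- c("qc", "normalize", "composition", "annotate", "markers",
                    "dominance", "heat")
step_deps <- list(
  qc = character(0), normalize = character(0), composition = character(0),
  annotate = "normalize", markers = "normalize",
  dominance = "normalize", heat = "normalize"
)

#' Pipeline configuration
#'
#' @param steps Ordered subset of `"qc"`, `"normalize"`, `"composition"`,
#'   `"annotate"`, `"markers"`, `"dominance"`, `"heat"`. Steps that need the
#'   lognorm layer require `"normalize"` to be requested before them.
#' @param simulate An [sim_config()] to generate the input, or `NULL` to read
#'   it from `input_dir`.
#' @param input_dir Directory readable by [read_sc_dataset()]; ignored when
#'   `simulate` is given.
#' @param marker_table Known-marker table for the annotate step (`cell_type`,
#'   `gene_id`); when simulating, defaults to the generator's planted markers.
#' @param out_dir Output directory for TSV/JSON artifacts (`NULL`: nothing
#'   written).
#' @param seed Seed for the simulate step (required with a simulate block;
#'   falls back to `simulate$seed`).
#' @param thresholds An [sc_thresholds()] bundle.
#' @return A list of class `sc_pipeline_config`.
#' @export
pipeline_config <- function(steps = pipeline_steps, simulate = NULL,
                            input_dir = NULL, marker_table = NULL,
                            out_dir = NULL, seed = NULL,
                            thresholds = sc_thresholds()) {
  steps <- match.arg(steps, pipeline_steps, several.ok = TRUE)
  for (s in steps) {
    need <- setdiff(step_deps[[s]], steps[seq_len(match(s, steps) - 1)])
    if (length(need)) {
      stop("step '", s, "' requires '", paste(need, collapse = "', '"),
           "' to run before it", call. = FALSE)
    }
  }
  if (is.null(simulate) && is.null(input_dir)) {
    stop("either a simulate block or an input_dir is required", call. = FALSE)
  }
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "sc_sim_config"))
    if (is.null(seed)) seed <- simulate$seed
    if (is.null(seed)) stop("a seed is required with a simulate block",
                            call. = FALSE)
  }
  structure(list(steps = steps, simulate = simulate, input_dir = input_dir,
                 marker_table = marker_table, out_dir = out_dir,
                 seed = seed, thresholds = thresholds),
            class = "sc_pipeline_config")
}

write_if <- function(tbl, out_dir, name, files) {
  if (is.null(out_dir)) return(files)
  path <- file.path(out_dir, name)
  readr::write_tsv(tbl, path)
  c(files, path)
}

#' Run the analysis pipeline
#'
#' Executes the requested steps in order on simulated or loaded data, writes
#' each step's tabular outputs (TSV) and a self-contained `report.json` into
#' `out_dir` when given, and returns the run report. Re-running with an
#' identical configuration and seed reproduces identical counts.
#'
#' @param config An [pipeline_config()].
#' @return A list of class `sc_run_report`: per-step `status`, a `counts`
#'   summary, `thresholds`, `seed`, `version` and the written `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sc_pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  status <- stats::setNames(rep("pending", length(config$steps)),
                            config$steps)
  counts <- list()
  files <- character(0)
  truth <- NULL
  marker_table <- config$marker_table

  report <- function(ok = TRUE) {
    rep <- structure(
      list(status = as.list(status), counts = counts,
           thresholds = unclass(config$thresholds), seed = config$seed,
           version = as.character(utils::packageVersion("sctriad")),
           files = files, ok = ok),
      class = "sc_run_report")
    if (!is.null(out_dir)) {
      jsonlite::write_json(unclass(rep), file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    rep
  }

  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate, seed = config$seed)
    ds <- sim$dataset
    truth <- sim$truth
    if (is.null(marker_table)) {
      marker_table <- tibble(
        cell_type = rep(names(truth$marker_genes),
                        lengths(truth$marker_genes)),
        gene_id = unlist(truth$marker_genes, use.names = FALSE))
    }
    if (!is.null(out_dir)) {
      files <- c(files, write_sc_dataset(ds, file.path(out_dir, "input")))
    }
  } else {
    ds <- read_sc_dataset(config$input_dir, thresholds = config$thresholds)
  }
  ds$thresholds <- config$thresholds
  counts$cells_input <- ncol(ds$counts)
  counts$genes_input <- nrow(ds$counts)

  run_step <- function(s, fun) {
    tryCatch({
      fun()
      status[[s]] <<- "ok"
    }, error = function(e) {
      status[[s]] <<- paste0("failed: ", conditionMessage(e))
      rep <- report(ok = FALSE)
      stop("pipeline step '", s, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  for (s in config$steps) {
    run_step(s, switch(
      s,
      qc = function() {
        ds <<- qc_filter_cells(ds)
        counts$cells_kept <<- ncol(ds$counts)
        files <<- write_if(qc_report(ds), out_dir, "qc_report.tsv", files)
      },
      normalize = function() {
        ds <<- log_normalize(ds)
      },
      composition = function() {
        comp <- cluster_composition(ds)
        counts$clusters <<- length(unique(comp$cluster_id))
        files <<- write_if(comp, out_dir, "composition.tsv", files)
      },
      annotate = function() {
        if (is.null(marker_table)) {
          stop("the annotate step needs a marker_table")
        }
        ann <- annotate_clusters(ds, marker_table)
        ds <<- set_cell_types(ds, ann)
        counts$clusters_annotated <<-
          sum(ann$assignments$cell_type != "unknown")
        files <<- write_if(ann$assignments, out_dir, "annotation.tsv", files)
        files <<- write_if(ann$dotplot, out_dir, "dotplot.tsv", files)
      },
      markers = function() {
        calls <- cluster_enriched_genes(ds)
        counts$cluster_enriched_calls <<- nrow(calls)
        files <<- write_if(calls, out_dir, "cluster_enriched.tsv", files)
        tm <- cell_type_markers(ds)
        counts$cell_type_marker_calls <<- nrow(tm)
        files <<- write_if(tm, out_dir, "cell_type_markers.tsv", files)
      },
      dominance = function() {
        dsub <- if (any(ds$cells$condition == "heat")) {
          filter_cells(ds, .data$condition == "control")
        } else ds
        calls <- dominance_calls(dsub)
        dc <- dominance_counts(calls)
        counts$dominance_calls <<- sum(!is.na(calls$dominant_subgenome))
        files <<- write_if(calls, out_dir, "dominance.tsv", files)
        files <<- write_if(dc, out_dir, "dominance_counts.tsv", files)
      },
      heat = function() {
        ht <- heat_deg_table(ds)
        counts$heat_degs <<- nrow(ht)
        files <<- write_if(ht, out_dir, "heat_degs.tsv", files)
        part <- deg_partition(ht)
        counts$heat_shared_up <<- length(part$shared_all$up)
        counts$heat_shared_down <<- length(part$shared_all$down)
        files <<- write_if(tidy(part), out_dir, "heat_partition.tsv", files)
        files <<- write_if(heat_marker_genes(part), out_dir,
                           "heat_markers.tsv", files)
        files <<- write_if(opposite_pattern_genes(ht), out_dir,
                           "heat_opposite.tsv", files)
        files <<- write_if(umi_shift_test(ds), out_dir, "umi_shift.tsv",
                           files)
        files <<- write_if(subgenome_deg_counts(ht, ds$genes), out_dir,
                           "subgenome_deg_counts.tsv", files)
      }
    ))
  }
  rep <- report(ok = TRUE)
  rep$truth <- truth
  rep
}

#' @export
print.sc_run_report <- function(x, ...) {
  cat("<sc_run_report> version", x$version, "seed", x$seed %||% NA, "\n")
  for (s in names(x$status)) cat("  ", s, ": ", x$status[[s]], "\n", sep = "")
  cat("  counts:\n")
  for (k in names(x$counts)) cat("    ", k, " = ", x$counts[[k]], "\n",
                                 sep = "")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `sc_run_report`.
#' @param ... Unused.
#' @export
tidy.sc_run_report <- function(x, ...) {
  tibble(metric = names(x$counts),
         value = as.numeric(unlist(x$counts)))
}

#' @rdname run_pipeline
#' @export
glance.sc_run_report <- function(x, ...) {
  tibble(ok = isTRUE(x$ok),
         n_steps = length(x$status),
         n_failed = sum(!vapply(x$status, identical, logical(1), "ok")),
         seed = x$seed %||% NA_integer_,
         version = x$version)
}
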