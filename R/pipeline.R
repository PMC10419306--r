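#' Pipeline configuration
#'
#' Bundles every stage's settings. Input is either a [sim_config] (the
#' simulator supplies counts, per-cell metadata, and cluster labels) or a
#' sample sheet plus a cell table giving donor, condition, and upstream
#' cluster ids per barcode (clustering itself is upstream and pluggable).
#' All randomness flows from the seeds recorded here.
#'
#' @param simulation A [sim_config], or `NULL` when ingesting real data.
#' @param sample_sheet Path to a sample sheet TSV (see [read_sample_sheet()]);
#'   ignored when `simulation` is given.
#' @param cells_path Path to a TSV with columns `barcode`, `sample_id`,
#'   `donor`, `condition`, `cluster`; required with `sample_sheet`.
#' @param qc A [qc_thresholds].
#' @param mito_prefix Mitochondrial symbol prefix.
#' @param downsample_to Per-sample cell target after first-pass QC (`NULL`
#'   disables), with `downsample_seed`.
#' @param downsample_seed Seed for downsampling.
#' @param markers Named marker list (see [read_marker_map()]).
#' @param gate `NULL`, or a list with `name`, `parent`, `gene_a`, `gene_b`,
#'   and optional `threshold` for the co-expression subtype gate.
#' @param de_alpha,de_method,de_pseudocount,de_min_pct,de_min_abs_log2fc
#'   Differential-expression settings (see [find_markers()]).
#' @param de_cell_types Cell types for the disease-vs-control DE runs
#'   (`NULL`: all annotated types).
#' @param gene_sets List of [directed_gene_set] for the enrichment stage
#'   (`NULL` skips it).
#' @param ges_significant_only,ges_normalizer GES options (see [ges()]).
#' @param tf_catalog Character vector of TF symbols (`NULL` skips the TF
#'   stage).
#' @param screen_outliers,grubbs_alpha,welch Composition options (see
#'   [composition_report()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            sample_sheet = NULL,
                            cells_path = NULL,
                            qc = qc_thresholds(),
                            mito_prefix = "MT-",
                            downsample_to = NULL,
                            downsample_seed = 1L,
                            markers = default_marker_map(),
                            gate = NULL,
                            de_alpha = 0.05,
                            de_method = "bonferroni",
                            de_pseudocount = 1,
                            de_min_pct = 0,
                            de_min_abs_log2fc = 0,
                            de_cell_types = NULL,
                            gene_sets = NULL,
                            ges_significant_only = TRUE,
                            ges_normalizer = "set",
                            tf_catalog = NULL,
                            screen_outliers = TRUE,
                            grubbs_alpha = 0.05,
                            welch = FALSE) {
  if (is.null(simulation) && is.null(sample_sheet)) {
    abort("supply either a simulation config or a sample sheet")
  }
  if (!is.null(sample_sheet) && is.null(simulation) && is.null(cells_path)) {
    abort("ingesting a sample sheet requires cells_path (donor/condition/cluster per barcode)")
  }
  structure(list(
    simulation = simulation, sample_sheet = sample_sheet,
    cells_path = cells_path, qc = qc, mito_prefix = mito_prefix,
    downsample_to = downsample_to, downsample_seed = as.integer(downsample_seed),
    markers = markers, gate = gate,
    de_alpha = de_alpha, de_method = de_method,
    de_pseudocount = de_pseudocount, de_min_pct = de_min_pct,
    de_min_abs_log2fc = de_min_abs_log2fc, de_cell_types = de_cell_types,
    gene_sets = gene_sets, ges_significant_only = ges_significant_only,
    ges_normalizer = ges_normalizer, tf_catalog = tf_catalog,
    screen_outliers = screen_outliers, grubbs_alpha = grubbs_alpha,
    welch = welch
  ), class = "pipeline_config")
}

#' Default end-to-end configuration for the simulated fixture
#'
#' Wires [default_fixture()] to QC thresholds, marker map, subtype gate,
#' gene sets, and TF catalog that exercise every stage.
#'
#' @param outlier,seed Passed to [default_fixture()].
#' @return A [pipeline_config].
#' @export
default_pipeline_config <- function(outlier = FALSE, seed = 1L) {
  pipeline_config(
    simulation = default_fixture(outlier = outlier, seed = seed),
    qc = qc_thresholds(
      min_features = 25, max_counts = 20000, max_pct_mito = 10,
      defer_mito = TRUE, mito_exempt_labels = "cardiomyocyte"
    ),
    gate = list(name = "Th17.1", parent = "Tcell",
                gene_a = "TBX21", gene_b = "RUNX1", threshold = 0),
    de_cell_types = "Tcell",
    gene_sets = default_gene_sets(),
    tf_catalog = default_tf_catalog()
  )
}

pipeline_stages <- c("simulate", "qc", "annotate", "de", "ges", "tfs", "composition")

#' Run the pipeline
#'
#' Executes the requested stages in dependency order:
#' simulate (or ingest) -> qc (first pass, with the mitochondrial cap
#' deferred when configured, then downsampling) -> annotate (normalization,
#' cluster annotation, the deferred mitochondrial pass, subtype gating) ->
#' de -> ges -> tfs -> composition. Each stage writes its tables under
#' `out_dir` and records them in `manifest.tsv` with MD5 hashes; a stage
#' whose upstream outputs are neither in memory nor on disk raises a
#' dependency error naming the stage. Reruns with an identical configuration
#' produce byte-identical outputs.
#'
#' @param config A [pipeline_config].
#' @param out_dir Output directory.
#' @param stages Subset of
#'   `c("simulate", "qc", "annotate", "de", "ges", "tfs", "composition")`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest tibble (`stage`, `file`, `md5`).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = pipeline_stages, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$manifest <- list()
  say <- function(...) if (!quiet) inform(sprintf(...))

  for (st in stages) {
    say("stage: %s", st)
    switch(st,
      simulate = stage_simulate(config, state, out_dir),
      qc = stage_qc(config, state, out_dir),
      annotate = stage_annotate(config, state, out_dir),
      de = stage_de(config, state, out_dir),
      ges = stage_ges(config, state, out_dir),
      tfs = stage_tfs(config, state, out_dir),
      composition = stage_composition(config, state, out_dir)
    )
  }
  manifest <- bind_rows(state$manifest)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}

record_file <- function(state, stage, path, rel = basename(path)) {
  state$manifest[[length(state$manifest) + 1]] <- tibble(
    stage = stage, file = rel,
    md5 = unname(tools::md5sum(path))
  )
}

write_stage_tsv <- function(state, stage, x, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  record_file(state, stage, path)
  path
}

dependency_error <- function(stage, needs) {
  abort(sprintf("stage '%s' requires outputs of stage '%s' (not in memory or in the output directory)",
                stage, needs))
}

stage_simulate <- function(config, state, out_dir) {
  if (!is.null(config$simulation)) {
    sim <- simulate_experiment(config$simulation)
    state$matrices <- sim$matrices
    state$cells <- sim$cells
    state$truth <- sim$truth
    for (donor in names(sim$matrices)) {
      paths <- write_mtx_triplet(sim$matrices[[donor]],
                                 file.path(out_dir, "counts", donor))
      for (p in paths) {
        record_file(state, "simulate", p,
                    rel = file.path("counts", donor, basename(p)))
      }
    }
    write_stage_tsv(state, "simulate", sim$cells, out_dir, "cells.tsv")
    write_stage_tsv(state, "simulate", sim$truth$planted, out_dir,
                    "truth_planted.tsv")
    write_stage_tsv(state, "simulate", sim$truth$weights, out_dir,
                    "truth_weights.tsv")
  } else {
    sheet <- read_sample_sheet(config$sample_sheet)
    state$matrices <- lapply(seq_len(nrow(sheet)), function(i) {
      d <- sheet$path[i]
      read_mtx_triplet(
        file.path(d, "matrix.mtx"), file.path(d, "features.tsv"),
        file.path(d, "barcodes.tsv"), sample_id = sheet$sample_id[i]
      )
    })
    names(state$matrices) <- sheet$sample_id
    state$cells <- readr::read_tsv(config$cells_path,
      col_types = readr::cols(cluster = "i", .default = "c"), progress = FALSE)
    write_stage_tsv(state, "simulate", state$cells, out_dir, "cells.tsv")
  }
  invisible(state)
}

load_counts_if_needed <- function(state, out_dir, stage) {
  if (!is.null(state$matrices)) return(invisible(state))
  counts_dir <- file.path(out_dir, "counts")
  cells_path <- file.path(out_dir, "cells.tsv")
  if (!dir.exists(counts_dir) || !file.exists(cells_path)) {
    dependency_error(stage, "simulate")
  }
  donors <- list.dirs(counts_dir, recursive = FALSE)
  state$matrices <- lapply(donors, function(d) {
    read_mtx_triplet(file.path(d, "matrix.mtx"), file.path(d, "features.tsv"),
                     file.path(d, "barcodes.tsv"), sample_id = basename(d))
  })
  names(state$matrices) <- basename(donors)
  state$cells <- readr::read_tsv(cells_path, show_col_types = FALSE,
                                 progress = FALSE)
  invisible(state)
}

stage_qc <- function(config, state, out_dir) {
  load_counts_if_needed(state, out_dir, "qc")
  metrics <- bind_rows(lapply(state$matrices, compute_qc_metrics,
                              mito_prefix = config$mito_prefix))
  qc_tab <- apply_qc_thresholds(metrics, config$qc)
  write_stage_tsv(state, "qc", qc_tab, out_dir, "qc_report.tsv")
  kept <- qc_tab$barcode[qc_tab$keep]
  state$matrices <- lapply(state$matrices, function(m) {
    m <- subset_cells(m, kept)
    if (!is.null(config$downsample_to)) {
      m <- downsample_cells(m, config$downsample_to, config$downsample_seed)
    }
    m
  })
  retained <- unlist(lapply(state$matrices, barcodes), use.names = FALSE)
  state$cells <- filter(state$cells, .data$barcode %in% retained)
  state$metrics <- filter(metrics, .data$barcode %in% retained)
  invisible(state)
}

merged_counts <- function(state) {
  mats <- lapply(state$matrices, function(m) m$counts)
  do.call(cbind, unname(mats))
}

stage_annotate <- function(config, state, out_dir) {
  if (is.null(state$matrices) || is.null(state$metrics)) {
    dependency_error("annotate", "qc")
  }
  counts <- merged_counts(state)
  cells <- state$cells[match(colnames(counts), state$cells$barcode), ]
  merged <- count_matrix(counts, sample_id = "merged")
  norm <- log_normalize(merged)
  ann <- annotate_clusters(norm, cells$cluster, config$markers)
  write_stage_tsv(state, "annotate", ann, out_dir, "annotation.tsv")
  cells <- label_cells(cells, ann)

  # second QC pass: deferred mitochondrial filtering on annotated labels
  if (config$qc$defer_mito && is.finite(config$qc$max_pct_mito)) {
    metrics <- state$metrics[match(cells$barcode, state$metrics$barcode), ]
    dm <- deferred_mito_filter(metrics, cells$cell_type, config$qc)
    write_stage_tsv(state, "annotate", dm, out_dir, "qc_deferred_report.tsv")
    keep <- dm$keep
    cells <- cells[keep, ]
    norm <- norm[, keep, drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
  }

  if (!is.null(config$gate)) {
    g <- config$gate
    flag <- coexpression_gate(counts, g$gene_a, g$gene_b,
                              threshold = g$threshold %||% 0)
    cells$is_subtype <- unname(flag[cells$barcode]) &
      (is.null(g$parent) | cells$cell_type == g$parent)
  }
  state$norm <- norm
  state$cells_annotated <- cells
  write_stage_tsv(state, "annotate", cells, out_dir, "cells_annotated.tsv")
  invisible(state)
}

ensure_annotated <- function(config, state, out_dir, stage) {
  if (!is.null(state$cells_annotated) && !is.null(state$norm)) {
    return(invisible(state))
  }
  path <- file.path(out_dir, "cells_annotated.tsv")
  if (!file.exists(path)) dependency_error(stage, "annotate")
  state$cells_annotated <- readr::read_tsv(path, show_col_types = FALSE,
                                           progress = FALSE)
  load_counts_if_needed(state, out_dir, stage)
  counts <- merged_counts(state)
  counts <- counts[, state$cells_annotated$barcode, drop = FALSE]
  state$norm <- log_normalize(count_matrix(counts, sample_id = "merged"))
  invisible(state)
}

stage_de <- function(config, state, out_dir) {
  ensure_annotated(config, state, out_dir, "de")
  cells <- state$cells_annotated
  types <- config$de_cell_types %||% sort(unique(cells$cell_type))
  state$de <- list()
  for (ct in types) {
    g1 <- cells$barcode[cells$cell_type == ct & cells$condition == "disease"]
    g2 <- cells$barcode[cells$cell_type == ct & cells$condition == "control"]
    if (length(g1) == 0 || length(g2) == 0) next
    de <- find_markers(
      state$norm, cells, g1, g2,
      alpha = config$de_alpha, method = config$de_method,
      pseudocount = config$de_pseudocount, min_pct = config$de_min_pct,
      min_abs_log2fc = config$de_min_abs_log2fc
    )
    state$de[[ct]] <- de
    write_stage_tsv(state, "de", de, out_dir, sprintf("de_%s.tsv", ct))
  }
  invisible(state)
}

load_de_if_needed <- function(state, out_dir, stage) {
  if (!is.null(state$de)) return(invisible(state))
  files <- list.files(out_dir, pattern = "^de_.*\\.tsv$", full.names = TRUE)
  if (length(files) == 0) dependency_error(stage, "de")
  state$de <- lapply(files, function(f) {
    x <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
    structure(x, class = c("sc_de", class(x)))
  })
  names(state$de) <- sub("^de_(.*)\\.tsv$", "\\1", basename(files))
  invisible(state)
}

stage_ges <- function(config, state, out_dir) {
  if (is.null(config$gene_sets)) return(invisible(state))
  load_de_if_needed(state, out_dir, "ges")
  tab <- ges_table(state$de, config$gene_sets,
                   significant_only = config$ges_significant_only,
                   normalizer = config$ges_normalizer)
  state$ges <- tab
  write_stage_tsv(state, "ges", tab, out_dir, "ges.tsv")
  invisible(state)
}

stage_tfs <- function(config, state, out_dir) {
  if (is.null(config$tf_catalog)) return(invisible(state))
  ensure_annotated(config, state, out_dir, "tfs")
  types <- config$de_cell_types %||% sort(unique(state$cells_annotated$cell_type))
  tab <- tf_specificity_by_type(
    state$norm, state$cells_annotated, config$tf_catalog,
    cell_types = types, alpha = config$de_alpha, method = config$de_method
  )
  state$tfs <- tab
  write_stage_tsv(state, "tfs", tab, out_dir, "tf_specificity.tsv")
  invisible(state)
}

stage_composition <- function(config, state, out_dir) {
  ensure_annotated(config, state, out_dir, "composition")
  cells <- state$cells_annotated
  pt <- proportion_table(cells, level = "cell_type")
  write_stage_tsv(state, "composition", pt, out_dir, "proportions_celltype.tsv")
  rep1 <- composition_report(pt, screen_outliers = config$screen_outliers,
                             alpha = config$grubbs_alpha, welch = config$welch)
  write_stage_tsv(state, "composition", rep1, out_dir,
                  "composition_celltype.tsv")
  state$composition <- rep1
  if (!is.null(config$gate) && "is_subtype" %in% names(cells)) {
    pt2 <- proportion_table(cells, level = "subtype",
                            parent = config$gate$parent,
                            subtype_name = config$gate$name %||% "subtype")
    write_stage_tsv(state, "composition", pt2, out_dir,
                    "proportions_subtype.tsv")
    rep2 <- composition_report(pt2, screen_outliers = config$screen_outliers,
                               alpha = config$grubbs_alpha,
                               welch = config$welch)
    write_stage_tsv(state, "composition", rep2, out_dir,
                    "composition_subtype.tsv")
    state$composition_subtype <- rep2
  }
  invisible(state)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `simulation:
#' default_fixture` (optionally with `outlier` and `seed`) requests the
#' built-in fixture, and `markers`, `gene_sets`, `tf_catalog` may be file
#' paths (read with [read_marker_map()], [read_gene_sets()],
#' [read_tf_catalog()]). `qc:` holds the [qc_thresholds()] fields.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulation <- NULL
  if (!is.null(y$simulation)) {
    if (identical(y$simulation, "default_fixture") ||
        identical(y$simulation$name, "default_fixture")) {
      simulation <- default_fixture(
        outlier = isTRUE(y$simulation$outlier),
        seed = y$simulation$seed %||% 1L
      )
    } else {
      abort("unknown simulation spec; use 'default_fixture' or build a sim_config in R")
    }
  }
  qc_args <- y$qc %||% list()
  qc <- do.call(qc_thresholds, qc_args)
  markers <- y$markers %||% default_marker_map()
  if (is.character(markers)) markers <- read_marker_map(markers)
  gene_sets <- y$gene_sets
  if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
  tf_catalog <- y$tf_catalog
  if (!is.null(tf_catalog) && length(tf_catalog) == 1 &&
      file.exists(tf_catalog)) {
    tf_catalog <- read_tf_catalog(tf_catalog)
  }
  args <- y[setdiff(names(y), c("simulation", "qc", "markers", "gene_sets",
                                "tf_catalog"))]
  do.call(pipeline_config, c(
    list(simulation = simulation, qc = qc, markers = markers,
         gene_sets = gene_sets, tf_catalog = tf_catalog),
    args
  ))
}
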