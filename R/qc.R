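#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of detected genes (`n_features`), the
#' total count (`n_counts`), and the percentage of counts from mitochondrial
#' genes (`pct_mito`), identified by symbol prefix. An all-zero cell has
#' `pct_mito` defined as 0.
#'
#' @param m A [count_matrix].
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes.
#' @return Tibble with columns `barcode`, `sample_id`, `n_features`,
#'   `n_counts`, `pct_mito`.
#' @export
#'
#' @examples
#' m <- count_matrix(matrix(c(3, 2, 5, 0, 0, 0), 3, 2,
#'   dimnames = list(c("geneA", "geneB", "MT-1"), c("c1", "c2"))), "s1")
#' compute_qc_metrics(m)
compute_qc_metrics <- function(m, mito_prefix = "MT-") {
  stopifnot(inherits(m, "count_matrix"))
  x <- m$counts
  n_counts <- Matrix::colSums(x)
  is_mito <- startsWith(rownames(x), mito_prefix)
  mito_counts <- if (any(is_mito)) Matrix::colSums(x[is_mito, , drop = FALSE]) else 0
  tibble(
    barcode = colnames(x),
    sample_id = m$sample_id,
    n_features = as.integer(Matrix::colSums(x > 0)),
    n_counts = as.numeric(n_counts),
    pct_mito = ifelse(n_counts > 0, 100 * mito_counts / n_counts, 0)
  )
}

#' QC thresholds
#'
#' Discard rules are strict inequalities — a cell exactly at a threshold is
#' kept ("less than" / "more than" / "higher than" semantics). With
#' `defer_mito = TRUE` the mitochondrial cap is not applied in the first pass;
#' it is deferred to [deferred_mito_filter()] after annotation, where cell
#' types in `mito_exempt_labels` (typically cardiomyocytes, which
#' physiologically carry high mitochondrial content) are exempt.
#'
#' @param min_features,max_features,max_counts,max_pct_mito Numeric bounds;
#'   leave unset (`-Inf`/`Inf`) to disable a rule.
#' @param defer_mito Defer the mitochondrial cap to the second pass.
#' @param mito_exempt_labels Cell-type labels exempt from the deferred cap.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = -Inf, max_features = Inf,
                          max_counts = Inf, max_pct_mito = Inf,
                          defer_mito = FALSE,
                          mito_exempt_labels = character()) {
  if (min_features > max_features) abort("min_features must be <= max_features")
  structure(list(
    min_features = min_features, max_features = max_features,
    max_counts = max_counts, max_pct_mito = max_pct_mito,
    defer_mito = defer_mito, mito_exempt_labels = mito_exempt_labels
  ), class = "qc_thresholds")
}

#' First-pass QC filtering
#'
#' Applies the feature, count, and (unless deferred) mitochondrial rules to a
#' metrics table. A cell is kept iff
#' `min_features <= n_features <= max_features`, `n_counts <= max_counts`,
#' and (`defer_mito` or `pct_mito <= max_pct_mito`). Boundary values are kept.
#'
#' @param metrics Tibble from [compute_qc_metrics()].
#' @param thresholds A [qc_thresholds].
#' @return The input tibble with logical `keep` and character `reason`
#'   (`NA` for kept cells; the first violated rule otherwise).
#' @export
apply_qc_thresholds <- function(metrics, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  t <- thresholds
  low <- metrics$n_features < t$min_features
  high <- metrics$n_features > t$max_features
  cnt <- metrics$n_counts > t$max_counts
  mito <- if (t$defer_mito) rep(FALSE, nrow(metrics))
          else metrics$pct_mito > t$max_pct_mito
  reason <- rep(NA_character_, nrow(metrics))
  reason[mito] <- "pct_mito above maximum"
  reason[cnt] <- "n_counts above maximum"
  reason[high] <- "n_features above maximum"
  reason[low] <- "n_features below minimum"
  metrics %>%
    mutate(keep = !(low | high | cnt | mito), reason = reason)
}

#' Second-pass (deferred) mitochondrial filtering
#'
#' Applies the mitochondrial cap using post-annotation labels: cells whose
#' label is in `mito_exempt_labels` always pass this filter; all other cells
#' are kept iff `pct_mito <= max_pct_mito`.
#'
#' @param metrics Tibble from [compute_qc_metrics()].
#' @param labels Character vector of cell-type labels, one per row of
#'   `metrics` (or a column name in `metrics`).
#' @param thresholds A [qc_thresholds] supplying `max_pct_mito` and
#'   `mito_exempt_labels`.
#' @return The metrics tibble with logical `keep` and character `reason`.
#' @export
deferred_mito_filter <- function(metrics, labels, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (is.character(labels) && length(labels) == 1 && labels %in% names(metrics)) {
    labels <- metrics[[labels]]
  }
  if (length(labels) != nrow(metrics)) {
    abort("labels must have one entry per cell")
  }
  if (anyNA(labels)) abort("every cell needs a cell-type label for deferred filtering")
  exempt <- labels %in% thresholds$mito_exempt_labels
  fail <- !exempt & metrics$pct_mito > thresholds$max_pct_mito
  metrics %>%
    mutate(
      keep = !fail,
      reason = ifelse(fail, "pct_mito above maximum (non-exempt type)", NA_character_)
    )
}

#' Downsample cells
#'
#' Uniform random subset of `min(n_cells, ncol)` cells without replacement,
#' keeping the original column order; counts and the gene list are untouched.
#' Deterministic under a fixed seed.
#'
#' @param m A [count_matrix].
#' @param n_cells Target number of cells (>= 0).
#' @param seed Integer seed.
#' @return A [count_matrix] with at most `n_cells` columns.
#' @export
downsample_cells <- function(m, n_cells, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"), n_cells >= 0)
  n <- ncol(m$counts)
  if (n_cells >= n) return(m)
  pick <- withr::with_seed(as.integer(seed), sort(sample.int(n, n_cells)))
  sub <- m$counts[, pick, drop = FALSE]
  # Matrix drops all dimnames when the subset is empty; restore them
  dimnames(sub) <- list(rownames(m$counts), colnames(m$counts)[pick])
  count_matrix(sub, sample_id = m$sample_id)
}

#' Subset a count matrix to a barcode set
#' @param m A [count_matrix].
#' @param keep Character vector of barcodes (order in `m` is preserved) or a
#'   logical vector over columns.
#' @return A [count_matrix].
#' @export
subset_cells <- function(m, keep) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.character(keep)) keep <- colnames(m$counts) %in% keep
  sub <- m$counts[, keep, drop = FALSE]
  dimnames(sub) <- list(rownames(m$counts), colnames(m$counts)[keep])
  count_matrix(sub, sample_id = m$sample_id)
}
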