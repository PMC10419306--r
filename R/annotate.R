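#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization followed by a log transform:
#' `log(1 + count * scale_factor / cell_total)`. An all-zero cell maps to an
#' all-zero column. Sparsity and within-cell rank order are preserved.
#'
#' @param m A [count_matrix].
#' @param scale_factor Positive scale (default 10,000).
#' @return A sparse `dgCMatrix` of normalized expression with the same
#'   dimnames as the counts.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "count_matrix"), scale_factor > 0)
  x <- m$counts
  totals <- Matrix::colSums(x)
  fac <- ifelse(totals > 0, scale_factor / totals, 0)
  out <- log1p(x %*% Matrix::Diagonal(x = fac, n = ncol(x)))
  dimnames(out) <- dimnames(x)
  methods::as(out, "CsparseMatrix")
}

#' Annotate clusters from marker expression
#'
#' Assigns each cluster the cell-type label whose marker genes have the
#' highest mean normalized expression over the cluster's cells. Exact ties go
#' to the earlier label in the marker map's declaration order (and are
#' logged). The full score matrix is returned for audit, so a human can
#' override an assignment.
#'
#' @param norm Normalized matrix from [log_normalize()] (genes x cells).
#' @param clusters Vector of cluster ids, one per column of `norm`.
#' @param markers Named list mapping cell-type label to marker gene symbols
#'   (see [read_marker_map()]). Markers absent from the matrix are ignored; a
#'   label with no marker present scores `-Inf` and is warned about.
#' @return Tibble with columns `cluster`, `label`, `tie` (logical), and one
#'   `score_<label>` column per candidate label.
#' @export
annotate_clusters <- function(norm, clusters, markers) {
  if (length(clusters) != ncol(norm)) {
    abort("clusters must have one entry per cell")
  }
  if (anyNA(clusters)) abort("every cell needs a cluster id")
  labels <- names(markers)
  present <- lapply(markers, intersect, x = rownames(norm))
  missing_lab <- labels[lengths(present) == 0]
  if (length(missing_lab)) {
    warn(paste0("no markers present in matrix for label(s): ",
                paste(missing_lab, collapse = ", ")))
  }
  ids <- unique(clusters)
  rows <- lapply(ids, function(cl) {
    cols <- which(clusters == cl)
    if (length(cols) == 0) abort(sprintf("cluster '%s' is empty", cl))
    sub <- norm[, cols, drop = FALSE]
    scores <- vapply(labels, function(lab) {
      g <- present[[lab]]
      if (length(g) == 0) return(-Inf)
      mean(Matrix::rowMeans(sub[g, , drop = FALSE]))
    }, numeric(1))
    best <- which(scores == max(scores))
    tie <- length(best) > 1
    if (tie) {
      inform(sprintf(
        "cluster '%s': score tie between %s; keeping '%s' (declaration order)",
        cl, paste(labels[best], collapse = ", "), labels[best[1]]
      ))
    }
    c(list(cluster = cl, label = labels[best[1]], tie = tie),
      setNames(as.list(scores), paste0("score_", labels)))
  })
  bind_rows(rows)
}

#' Attach cluster labels to a cell table
#'
#' @param cells Tibble with a `cluster` column.
#' @param annotation Result of [annotate_clusters()].
#' @return `cells` with a `cell_type` column.
#' @export
label_cells <- function(cells, annotation) {
  cells %>%
    left_join(select(annotation, "cluster", cell_type = "label"), by = "cluster")
}

#' Co-expression subtype gate
#'
#' Flags cells expressing both gating genes: any nonzero value in each. The
#' paper context is the Th17.1 T-cell state, transcriptionally gated as
#' TBX21+RUNX1+ cells; the gate is threshold-free because a positivity gate
#' is invariant to log-normalization.
#'
#' @param mat Count or normalized matrix (genes x cells); [count_matrix]
#'   accepted.
#' @param gene_a,gene_b Gating gene symbols.
#' @param threshold Expression strictly above this counts as positive
#'   (default 0).
#' @return Named logical vector over cells.
#' @export
coexpression_gate <- function(mat, gene_a, gene_b, threshold = 0) {
  if (inherits(mat, "count_matrix")) mat <- mat$counts
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(mat)) {
      abort(sprintf("gating gene '%s' is absent from the matrix", g))
    }
  }
  a <- as.numeric(mat[gene_a, ]) > threshold
  b <- as.numeric(mat[gene_b, ]) > threshold
  setNames(a & b, colnames(mat))
}

#' Marker AUC (ROC analysis)
#'
#' Area under the ROC curve for one gene as a classifier of a positive cell
#' set: the Mann-Whitney statistic `U / (n_pos * n_neg)`, ties counted 1/2 —
#' the probability that a random positive cell expresses the gene more highly
#' than a random negative cell.
#'
#' @param mat Expression matrix (genes x cells), or a numeric vector of the
#'   gene's expression.
#' @param positive Logical vector: the positive cell set.
#' @param gene Gene symbol (ignored when `mat` is a vector).
#' @return AUC in `[0, 1]`.
#' @export
marker_auc <- function(mat, positive, gene = NULL) {
  if (inherits(mat, "count_matrix")) mat <- mat$counts
  x <- if (is.null(dim(mat))) as.numeric(mat) else {
    if (!gene %in% rownames(mat)) abort(sprintf("gene '%s' absent from matrix", gene))
    as.numeric(mat[gene, ])
  }
  if (length(positive) != length(x)) abort("positive mask must cover every cell")
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    abort("positive mask is degenerate: need at least one positive and one negative cell")
  }
  r <- rank(x)
  u <- sum(r[positive]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}
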