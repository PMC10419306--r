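#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by the null rank-sum distribution when both groups have at
#' most `exact_limit` observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. Symmetric in
#' its arguments.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_limit Largest group size for which the exact distribution is
#'   used (default 8).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
#'
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # exact: 0.1
rank_sum_test <- function(a, b, exact_limit = 8) {
  na <- length(a)
  nb <- length(b)
  if (na == 0 || nb == 0) abort("both groups must be non-empty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && na <= exact_limit && nb <= exact_limit) {
    p <- 2 * min(pwilcox(u, na, nb), 1 - pwilcox(u - 1, na, nb))
    return(min(1, p))
  }
  n <- na + nb
  tie_tab <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1) # all observations tied
  z <- u - na * nb / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction toward 0
  min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
}

#' Log2 average fold change (Seurat convention)
#'
#' Fold change of de-logged group means with a pseudocount:
#' `log2((mean(expm1(a)) + pc) / (mean(expm1(b)) + pc))`, where `a` and `b`
#' are log1p-scale normalized expression vectors.
#'
#' @param norm_a,norm_b Normalized (log1p-scale) expression vectors.
#' @param pseudocount Positive pseudocount (default 1).
#' @return Signed log2 fold change (group a over group b).
#' @export
log2_avg_fold_change <- function(norm_a, norm_b, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  log2((mean(expm1(norm_a)) + pseudocount) / (mean(expm1(norm_b)) + pseudocount))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up over the genes
#' tested.
#'
#' @param p Vector of raw p-values in `(0, 1]`.
#' @param method `"bonferroni"` (default, matching Seurat's FindMarkers
#'   adjusted p) or `"bh"`.
#' @return Adjusted p-values.
#' @export
adjust_p <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

resolve_selector <- function(selector, cells, barcodes) {
  if (is.logical(selector)) {
    stopifnot(length(selector) == length(barcodes))
    return(barcodes[selector])
  }
  if (is.function(selector)) {
    keep <- selector(cells)
    if (is.logical(keep)) return(cells$barcode[keep])
    return(keep)
  }
  as.character(selector) # barcode vector
}

#' Per-gene differential expression between two cell groups
#'
#' Wilcoxon rank-sum test on normalized expression, Seurat-convention log2
#' average fold change (group 1 over group 2), detection percentages, and
#' multiple-testing adjustment over all genes tested. Optional detection and
#' fold-change pre-filters default off: by default every gene is tested and
#' the adjustment spans all of them.
#'
#' @param norm Normalized matrix from [log_normalize()].
#' @param cells Cell table with `barcode` (used by function selectors).
#' @param group1,group2 Cell selectors: barcode vectors, logical masks over
#'   the matrix columns, or functions of `cells` returning either. The groups
#'   must be disjoint and non-empty.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param method Adjustment method, `"bonferroni"` or `"bh"`.
#' @param pseudocount Fold-change pseudocount.
#' @param min_pct Minimum detection fraction (in either group, percent scale)
#'   for a gene to be tested; 0 disables.
#' @param min_abs_log2fc Minimum |log2 fold change| for a gene to be tested;
#'   0 disables.
#' @return A tibble of class `sc_de` with columns `gene`, `log2_fc`,
#'   `p_value`, `p_adjusted`, `pct_1`, `pct_2`, `significant`, and attributes
#'   `n1`, `n2`, `alpha`, `method`, `n_genes_tested`, `prefiltered`.
#' @export
find_markers <- function(norm, cells, group1, group2, alpha = 0.05,
                         method = c("bonferroni", "bh"), pseudocount = 1,
                         min_pct = 0, min_abs_log2fc = 0) {
  method <- match.arg(method)
  bcs <- colnames(norm)
  g1 <- resolve_selector(group1, cells, bcs)
  g2 <- resolve_selector(group2, cells, bcs)
  g1 <- intersect(g1, bcs)
  g2 <- intersect(g2, bcs)
  if (length(g1) == 0 || length(g2) == 0) abort("both groups must be non-empty")
  if (length(intersect(g1, g2))) abort("group selectors overlap")

  m1 <- as.matrix(norm[, g1, drop = FALSE])
  m2 <- as.matrix(norm[, g2, drop = FALSE])
  n1 <- length(g1)
  n2 <- length(g2)

  pct1 <- 100 * rowSums(m1 > 0) / n1
  pct2 <- 100 * rowSums(m2 > 0) / n2
  fc <- log2((rowMeans(expm1(m1)) + pseudocount) /
               (rowMeans(expm1(m2)) + pseudocount))

  tested <- rep(TRUE, nrow(norm))
  if (min_pct > 0) tested <- tested & (pct1 >= min_pct | pct2 >= min_pct)
  if (min_abs_log2fc > 0) tested <- tested & abs(fc) >= min_abs_log2fc

  idx <- which(tested)
  p <- vapply(idx, function(i) rank_sum_test(m1[i, ], m2[i, ]), numeric(1))
  out <- tibble(
    gene = rownames(norm)[idx],
    log2_fc = fc[idx],
    p_value = p,
    p_adjusted = adjust_p(p, method),
    pct_1 = pct1[idx],
    pct_2 = pct2[idx]
  ) %>%
    mutate(significant = .data$p_adjusted < alpha)
  structure(out,
    class = c("sc_de", class(out)),
    n1 = n1, n2 = n2, alpha = alpha, method = method,
    n_genes_tested = length(idx),
    prefiltered = min_pct > 0 || min_abs_log2fc > 0
  )
}

#' @export
tidy.sc_de <- function(x, ...) as_tibble(x)

#' @export
glance.sc_de <- function(x, ...) {
  tibble(
    n_genes_tested = attr(x, "n_genes_tested"),
    n_significant = sum(x$significant),
    n1 = attr(x, "n1"), n2 = attr(x, "n2"),
    alpha = attr(x, "alpha"), method = attr(x, "method"),
    prefiltered = attr(x, "prefiltered")
  )
}

#' Volcano plot of a differential-expression result
#' @param object An `sc_de` table from [find_markers()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sc_de <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$log2_fc, -log10(.data$p_adjusted),
                 colour = .data$significant)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = expression(log[2] ~ "average fold change"),
      y = expression(-log[10] ~ "adjusted p"), colour = "significant"
    ) +
    ggplot2::theme_minimal()
}
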