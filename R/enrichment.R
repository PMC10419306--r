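#' Direction-adjust fold changes for a gene set
#'
#' Joins a DE table to a directed gene set: activators keep their log2 fold
#' change, repressors have the sign inverted (a repressor moving down pushes
#' its pathway up). Set members absent from the DE table are dropped and
#' reported via the `dropped` attribute.
#'
#' @param de An `sc_de` table (or any tibble with `gene`, `log2_fc`, and
#'   optionally `significant`).
#' @param set A [directed_gene_set].
#' @return Tibble with `gene`, `direction`, `log2_fc`, `adjusted_log2_fc`
#'   (and `significant` if present in `de`); attribute `dropped` lists the
#'   absent members.
#' @export
adjust_directions <- function(de, set) {
  stopifnot(inherits(set, "directed_gene_set"))
  de <- as_tibble(de)
  joined <- set$members %>%
    left_join(de, by = "gene")
  present <- joined %>%
    filter(!is.na(.data$log2_fc)) %>%
    mutate(adjusted_log2_fc = ifelse(.data$direction == "repressor",
                                     -.data$log2_fc, .data$log2_fc))
  keep <- intersect(c("gene", "direction", "log2_fc", "adjusted_log2_fc",
                      "significant"), names(present))
  structure(present[, keep], dropped = setdiff(set$members$gene, present$gene))
}

#' Gene enrichment score (GES)
#'
#' The signed, max-normalized enrichment score for a directed gene set over a
#' differential-expression result:
#' \deqn{GES = \sum_{i=1}^{G} \frac{adjFC_i}{\max_i |adjFC_i|}}
#' where \eqn{adjFC_i} is the log2 average fold change of set gene *i* after
#' repressor sign inversion, the maximum runs over the same entering genes,
#' and *G* counts the genes entering the score. Positive scores indicate the
#' set is upregulated in group 1. By default only genes significant in the DE
#' result (adjusted p below its alpha) enter the score, matching a retention
#' rule of adjusted p < 0.05 applied before enrichment.
#'
#' @param de An `sc_de` table from [find_markers()].
#' @param set A [directed_gene_set].
#' @param significant_only If `TRUE` (default), only DE-significant set genes
#'   enter.
#' @param normalizer `"set"` (default): the max |adjusted fold change| is
#'   taken within the entering set genes; `"global"`: across all genes in the
#'   DE table (sign-adjusted values for the set, raw magnitudes elsewhere).
#' @return A list of class `ges_record`: `name`, `ges`, `G_scored`,
#'   `G_declared`, `normalizer_value`, `contributions` (per-gene tibble), and
#'   `dropped`.
#' @export
#'
#' @examples
#' de <- tibble::tibble(
#'   gene = c("A", "B", "C", "D"),
#'   log2_fc = c(1, -0.5, -0.5, 0.25),
#'   p_value = 0.001, p_adjusted = 0.001,
#'   pct_1 = 50, pct_2 = 50, significant = TRUE
#' )
#' s <- directed_gene_set("demo", c("A", "B", "C", "D"),
#'   c("activator", "activator", "repressor", "activator"))
#' ges(de, s)$ges # 1.25
ges <- function(de, set, significant_only = TRUE,
                normalizer = c("set", "global")) {
  normalizer <- match.arg(normalizer)
  adj <- adjust_directions(de, set)
  entering <- adj
  if (significant_only) {
    if (!"significant" %in% names(adj)) {
      abort("DE table has no 'significant' column; run find_markers() or set significant_only = FALSE")
    }
    entering <- filter(adj, .data$significant)
  }
  if (nrow(entering) == 0) abort("empty gene set after filtering")
  norm_value <- if (normalizer == "set") {
    max(abs(entering$adjusted_log2_fc))
  } else {
    max(abs(as_tibble(de)$log2_fc))
  }
  if (norm_value == 0) abort("degenerate normalizer: all entering fold changes are 0")
  contributions <- entering %>%
    mutate(contribution = .data$adjusted_log2_fc / norm_value)
  structure(list(
    name = set$name,
    ges = sum(contributions$contribution),
    G_scored = nrow(contributions),
    G_declared = nrow(set$members),
    normalizer_value = norm_value,
    contributions = contributions,
    dropped = attr(adj, "dropped")
  ), class = "ges_record")
}

#' @export
print.ges_record <- function(x, ...) {
  cat(sprintf("<ges_record> '%s': GES = %.4f over G = %d genes (declared %d)\n",
              x$name, x$ges, x$G_scored, x$G_declared))
  invisible(x)
}

#' @export
tidy.ges_record <- function(x, ...) x$contributions

#' @export
glance.ges_record <- function(x, ...) {
  tibble(set = x$name, ges = x$ges, G_scored = x$G_scored,
         G_declared = x$G_declared, normalizer_value = x$normalizer_value,
         n_dropped = length(x$dropped))
}

#' GES over multiple comparisons and sets
#'
#' Scores every (comparison, set) pair; pairs whose score is not computable
#' (no entering genes, or a degenerate normalizer) are listed with the reason
#' rather than aborting the table.
#'
#' @param de_list Named list of `sc_de` tables, one per comparison.
#' @param sets List of [directed_gene_set].
#' @param ... Passed to [ges()].
#' @return Tibble of class `sc_ges` with columns `comparison`, `set`,
#'   `G_scored`, `G_declared`, `ges`, `status` (`"ok"` or the failure
#'   reason).
#' @export
ges_table <- function(de_list, sets, ...) {
  if (inherits(de_list, "sc_de")) de_list <- list(comparison = de_list)
  rows <- list()
  for (cmp in names(de_list)) {
    for (s in sets) {
      rec <- tryCatch(ges(de_list[[cmp]], s, ...), error = identity)
      rows[[length(rows) + 1]] <- if (inherits(rec, "error")) {
        tibble(comparison = cmp, set = s$name, G_scored = NA_integer_,
               G_declared = nrow(s$members), ges = NA_real_,
               status = conditionMessage(rec))
      } else {
        tibble(comparison = cmp, set = rec$name, G_scored = rec$G_scored,
               G_declared = rec$G_declared, ges = rec$ges, status = "ok")
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(comparison = character(), set = character(),
                  G_scored = integer(), G_declared = integer(),
                  ges = numeric(), status = character())
  }
  structure(out, class = c("sc_ges", class(out)))
}

#' Bar chart of enrichment scores
#' @param object An `sc_ges` table from [ges_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sc_ges <- function(object, ...) {
  dat <- filter(as_tibble(object), .data$status == "ok")
  ggplot2::ggplot(dat, ggplot2::aes(.data$ges, .data$set, fill = .data$ges > 0)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
      labels = c(`TRUE` = "up", `FALSE` = "down")
    ) +
    ggplot2::labs(x = "gene enrichment score", y = NULL, fill = "direction") +
    ggplot2::theme_minimal()
}
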