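#' Condition-specific transcription factors
#'
#' Filters a pair of per-condition differential-expression runs (the same
#' contrast — typically one cell type against all others — computed separately
#' within the disease and the control cells) down to catalog transcription
#' factors that are significant in disease but not in control. A TF absent
#' from the control table (e.g., undetected there) counts as not significant
#' in control and is recorded as `"untested"`.
#'
#' @param de_disease,de_control `sc_de` tables for the same contrast within
#'   each condition.
#' @param catalog Character vector of TF symbols (see [read_tf_catalog()]).
#' @param alpha Significance level in `(0, 1)` (default 0.05).
#' @return Tibble of class `sc_tf` with columns `gene`, `disease_p_adjusted`,
#'   `disease_log2_fc`, `control_p_adjusted` (`NA` when untested),
#'   `control_status` (`"n.s."` or `"untested"`); attribute `alpha`.
#' @export
condition_specific_tfs <- function(de_disease, de_control, catalog,
                                   alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)")
  }
  dis <- as_tibble(de_disease)
  ctl <- as_tibble(de_control)
  out <- dis %>%
    filter(.data$gene %in% catalog, .data$p_adjusted < alpha) %>%
    select("gene", disease_p_adjusted = "p_adjusted",
           disease_log2_fc = "log2_fc") %>%
    left_join(select(ctl, "gene", control_p_adjusted = "p_adjusted"),
              by = "gene") %>%
    mutate(control_status = ifelse(is.na(.data$control_p_adjusted),
                                   "untested", "n.s.")) %>%
    filter(is.na(.data$control_p_adjusted) | .data$control_p_adjusted >= alpha)
  structure(out, class = c("sc_tf", class(out)), alpha = alpha)
}

#' Condition-specific TFs across cell types
#'
#' Runs the cell-type-versus-rest contrast separately within each condition
#' and applies [condition_specific_tfs()] per cell type.
#'
#' @param norm Normalized matrix from [log_normalize()].
#' @param cells Cell table with `barcode`, `condition`, `cell_type`.
#' @param catalog Character vector of TF symbols.
#' @param cell_types Cell types to analyse (default: all present).
#' @param alpha Significance level.
#' @param ... Passed to [find_markers()].
#' @return Tibble: `cell_type` plus the [condition_specific_tfs()] columns.
#' @export
tf_specificity_by_type <- function(norm, cells, catalog,
                                   cell_types = NULL, alpha = 0.05, ...) {
  if (is.null(cell_types)) cell_types <- sort(unique(cells$cell_type))
  rows <- lapply(cell_types, function(ct) {
    per_condition <- lapply(c("disease", "control"), function(cond) {
      sub <- filter(cells, .data$condition == cond)
      g1 <- sub$barcode[sub$cell_type == ct]
      g2 <- sub$barcode[sub$cell_type != ct]
      if (length(g1) == 0 || length(g2) == 0) return(NULL)
      find_markers(norm, sub, g1, g2, alpha = alpha, ...)
    })
    if (is.null(per_condition[[1]]) || is.null(per_condition[[2]])) return(NULL)
    res <- condition_specific_tfs(per_condition[[1]], per_condition[[2]],
                                  catalog, alpha)
    if (nrow(res) == 0) return(NULL)
    mutate(as_tibble(res), cell_type = ct, .before = 1)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(cell_type = character(), gene = character(),
                  disease_p_adjusted = numeric(), disease_log2_fc = numeric(),
                  control_p_adjusted = numeric(), control_status = character())
  }
  structure(out, class = c("sc_tf", class(out)), alpha = alpha)
}
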