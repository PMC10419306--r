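#' Per-donor cell-type proportion table
#'
#' Counts cells per donor and label and converts to proportions. At the
#' default `"cell_type"` level the denominator is the donor's total cell
#' count and proportions per donor sum to 1 over the labels (absent labels
#' appear with proportion 0). At the `"subtype"` level the denominator is the
#' donor's parent-type population, and two rows are emitted per donor (the
#' subtype and its complement) so the sum-to-one invariant holds there too;
#' donors with no parent-type cells are excluded with a warning.
#'
#' @param cells Cell table with `donor`, `condition`, and the label columns.
#' @param level `"cell_type"` or `"subtype"`.
#' @param parent Parent cell type (required at subtype level).
#' @param subtype_col Logical column flagging subtype membership (default
#'   `"is_subtype"`).
#' @param subtype_name Label used for the subtype rows.
#' @return Tibble with columns `donor`, `condition`, `cell_type`, `n_cells`,
#'   `proportion`.
#' @export
proportion_table <- function(cells, level = c("cell_type", "subtype"),
                             parent = NULL, subtype_col = "is_subtype",
                             subtype_name = "subtype") {
  level <- match.arg(level)
  if (level == "cell_type") {
    tallies <- cells %>%
      count(.data$donor, .data$condition, .data$cell_type, name = "n_cells")
    grid <- tidyr::expand_grid(
      distinct(cells, .data$donor, .data$condition),
      cell_type = unique(cells$cell_type)
    )
    out <- grid %>%
      left_join(tallies, by = c("donor", "condition", "cell_type")) %>%
      mutate(n_cells = tidyr::replace_na(.data$n_cells, 0L)) %>%
      group_by(.data$donor) %>%
      mutate(proportion = .data$n_cells / sum(.data$n_cells)) %>%
      ungroup()
    return(arrange(out, .data$donor, .data$cell_type))
  }
  if (is.null(parent)) abort("subtype level needs a parent cell type")
  if (!subtype_col %in% names(cells)) {
    abort(sprintf("cells has no '%s' column", subtype_col))
  }
  pool <- filter(cells, .data$cell_type == parent)
  dropped <- setdiff(unique(cells$donor), unique(pool$donor))
  if (length(dropped)) {
    warn(paste0("donor(s) with no '", parent, "' cells excluded: ",
                paste(dropped, collapse = ", ")))
  }
  agg <- pool %>%
    group_by(.data$donor, .data$condition) %>%
    summarise(
      n_parent = n(), n_sub = sum(.data[[subtype_col]]), .groups = "drop"
    )
  bind_rows(
    dplyr::transmute(agg, donor = .data$donor, condition = .data$condition,
                     cell_type = subtype_name, n_cells = .data$n_sub,
                     proportion = .data$n_sub / .data$n_parent),
    dplyr::transmute(agg, donor = .data$donor, condition = .data$condition,
                     cell_type = paste0("non-", subtype_name),
                     n_cells = .data$n_parent - .data$n_sub,
                     proportion = 1 - .data$n_sub / .data$n_parent)
  ) %>%
    arrange(.data$donor, .data$cell_type)
}

#' Pooled-variance two-sample t test
#'
#' Student's two-sample t test with pooled variance on per-donor values,
#' `df = n1 + n2 - 2`; the statistic is `mean(control) - mean(disease)` over
#' its standard error. A zero pooled variance is flagged rather than an
#' error: identical constants give `t = 0, p = 1`; differing constants give
#' `p = 0`.
#'
#' @param props_control,props_disease Numeric vectors (>= 2 values each).
#' @param welch Use Welch's unequal-variance t instead (off by default).
#' @return List with `t`, `p`, `df`, and `flag` (`NA` or `"zero variance"`).
#' @export
student_t_test <- function(props_control, props_disease, welch = FALSE) {
  x <- props_control
  y <- props_disease
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("insufficient donors: need at least 2 per condition")
  if (welch) {
    se2 <- var(x) / n1 + var(y) / n2
    if (se2 == 0) {
      return(degenerate_t(mean(x), mean(y)))
    }
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
    if (sp2 == 0) {
      return(degenerate_t(mean(x), mean(y)))
    }
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tt, p = 2 * pt(-abs(tt), df), df = df, flag = NA_character_)
}

degenerate_t <- function(m1, m2) {
  if (m1 == m2) list(t = 0, p = 1, df = NA_real_, flag = "zero variance")
  else list(t = sign(m1 - m2) * Inf, p = 0, df = NA_real_, flag = "zero variance")
}

#' Significance tier of a composition p-value
#'
#' `"*"` for p < 0.05 (significant), `"‡"` for 0.05 <= p < 0.1
#' (trending), `"n.s."` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of tiers.
#' @export
classify_tier <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.05 ~ "*",
    p < 0.1 ~ "‡",
    TRUE ~ "n.s."
  )
}

#' Grubbs single-outlier test
#'
#' Tests the most extreme observation: `G = max|x - mean| / sd`, compared to
#' the two-sided critical value at `alpha` derived from the t distribution,
#' \deqn{\frac{n-1}{\sqrt n}\sqrt{\frac{t^2_{\alpha/(2n),\,n-2}}{n-2+t^2_{\alpha/(2n),\,n-2}}}.}
#' At most one outlier is flagged per call.
#'
#' @param values Numeric vector, length >= 3, with positive standard
#'   deviation.
#' @param alpha Significance level (default 0.05).
#' @return List with `outlier_index` (`NA` if none), `G`, `critical`, and
#'   `value`.
#' @export
#'
#' @examples
#' grubbs_test(c(1, 1, 1, 10))$outlier_index # 4
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) abort("Grubbs test needs at least 3 values")
  s <- sd(values)
  if (s == 0) abort("Grubbs test is undefined for zero-variance data")
  dev <- abs(values - mean(values))
  idx <- which.max(dev)
  g <- dev[idx] / s
  crit <- grubbs_critical(n, alpha)
  list(
    outlier_index = if (g > crit) idx else NA_integer_,
    G = g, critical = crit, value = values[idx]
  )
}

#' Grubbs critical value
#' @param n Sample size (>= 3).
#' @param alpha Two-sided significance level.
#' @return The critical value of G.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  tcrit <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
}

#' Composition report across cell types
#'
#' For each cell type: optional Grubbs screening of per-donor proportions
#' within each condition (a flagged donor is removed for that cell type's
#' test only, and logged), then the pooled-variance t test of control versus
#' disease donor proportions and tier classification. If, after screening,
#' either condition retains fewer than 2 donors, or all of a condition's
#' remaining proportions are zero (no donor of that condition contains the
#' population, the situation in which a comparison cannot be supported), the
#' test is skipped with status `"insufficient donors"`.
#'
#' @param pt Proportion table from [proportion_table()].
#' @param screen_outliers Run per-(cell type, condition) Grubbs screening
#'   (default `TRUE`).
#' @param alpha Tier alpha is fixed by [classify_tier()]; this `alpha` is the
#'   Grubbs screening level (default 0.05).
#' @param welch Use Welch's t instead of pooled-variance Student's t.
#' @return Tibble of class `sc_composition`: `cell_type`, `n_control`,
#'   `n_disease`, `mean_control`, `mean_disease`, `fold_change`
#'   (disease over control), `t`, `p`, `tier`, `removed_donors`
#'   (comma-separated), `status`, `flag`.
#' @export
composition_report <- function(pt, screen_outliers = TRUE, alpha = 0.05,
                               welch = FALSE) {
  rows <- lapply(unique(pt$cell_type), function(ct) {
    sub <- filter(pt, .data$cell_type == ct)
    removed <- character()
    groups <- lapply(c("control", "disease"), function(cond) {
      g <- filter(sub, .data$condition == cond)
      vals <- setNames(g$proportion, g$donor)
      if (screen_outliers && length(vals) >= 3 && sd(vals) > 0) {
        gt <- grubbs_test(unname(vals), alpha)
        if (!is.na(gt$outlier_index)) {
          removed <<- c(removed, names(vals)[gt$outlier_index])
          vals <- vals[-gt$outlier_index]
        }
      }
      vals
    })
    ctl <- groups[[1]]
    dis <- groups[[2]]
    base <- tibble(
      cell_type = ct,
      n_control = length(ctl), n_disease = length(dis),
      mean_control = mean(ctl), mean_disease = mean(dis),
      fold_change = mean(dis) / mean(ctl),
      removed_donors = paste(removed, collapse = ",")
    )
    if (length(ctl) < 2 || length(dis) < 2 ||
        all(ctl == 0) || all(dis == 0)) {
      return(mutate(base, t = NA_real_, p = NA_real_, tier = NA_character_,
                    status = "insufficient donors", flag = NA_character_))
    }
    res <- student_t_test(ctl, dis, welch = welch)
    mutate(base, t = res$t, p = res$p, tier = classify_tier(res$p),
           status = "ok", flag = res$flag)
  })
  out <- bind_rows(rows) %>%
    select("cell_type", "n_control", "n_disease", "mean_control",
           "mean_disease", "fold_change", "t", "p", "tier",
           "removed_donors", "status", "flag")
  structure(out, class = c("sc_composition", class(out)))
}

#' @export
tidy.sc_composition <- function(x, ...) as_tibble(x)

#' @export
glance.sc_composition <- function(x, ...) {
  tibble(
    n_cell_types = nrow(x),
    n_significant = sum(x$tier == "*", na.rm = TRUE),
    n_trending = sum(x$tier == "‡", na.rm = TRUE),
    n_skipped = sum(x$status != "ok"),
    n_donors_removed = sum(nzchar(x$removed_donors))
  )
}

#' Plot a composition report against its proportion table
#'
#' Per-donor proportions by condition, one panel per cell type, with the
#' tier symbol in the panel strip.
#'
#' @param object An `sc_composition` from [composition_report()].
#' @param pt The [proportion_table()] the report was computed from.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sc_composition <- function(object, pt, ...) {
  lab <- as_tibble(object) %>%
    mutate(panel = paste0(.data$cell_type,
                          ifelse(is.na(.data$tier) | .data$tier == "n.s.",
                                 "", paste0(" ", .data$tier))))
  dat <- left_join(pt, select(lab, "cell_type", "panel"), by = "cell_type")
  ggplot2::ggplot(dat, ggplot2::aes(.data$condition, .data$proportion)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "proportion of cells") +
    ggplot2::theme_minimal()
}
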