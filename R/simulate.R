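#' Simulation configuration
#'
#' Describes a multi-donor, two-condition single-cell experiment: cell-type
#' mixtures with a condition-dependent proportion shift and per-donor Dirichlet
#' jitter, negative-binomial counts with log-normal library sizes,
#' cell-type-dependent mitochondrial content, planted differentially expressed
#' genes, an optional rare co-expressing subtype, and an optional outlier donor.
#'
#' Counts for gene g in cell i of type t are negative binomial with mean
#' `library_size_i * expression_{g,t} * 2^beta` (beta only where a DE effect is
#' planted for that gene, type, and condition) and size parameter `dispersion`
#' (so variance = mu + mu^2/dispersion; large `dispersion` approaches Poisson).
#' Each type's relative expression profile is normalized so that mitochondrial
#' genes carry `mito_level[type]` of the total and the remaining genes share
#' the rest.
#'
#' @param genes Character vector of gene symbols (mitochondrial genes carry the
#'   `mito_prefix`).
#' @param cell_types Named list; each element a list with `markers` (character)
#'   and `profile` (non-negative numeric named by the non-mitochondrial genes;
#'   relative units, normalized internally).
#' @param weights_control Named numeric mixture weights per cell type
#'   (normalized internally).
#' @param proportion_shift Named numeric multiplicative change of each type's
#'   weight in disease (types absent default to 1).
#' @param donors Tibble with columns `donor`, `condition`
#'   (`control`/`disease`), `n_cells`.
#' @param de_effects Tibble with columns `cell_type`, `gene`, `condition`
#'   (`control`, `disease`, or `both`), `beta` (log2 effect).
#' @param subtype `NULL`, or a list with `name`, `parent` (cell type),
#'   `gene_a`, `gene_b` (gating genes), `freq_control`, `freq_disease`
#'   (membership frequencies within the parent type), and `level` (relative
#'   expression each gating gene receives in subtype cells).
#' @param mito_level Named numeric, expected mitochondrial count fraction per
#'   cell type.
#' @param mito_profile Optional relative weights across mitochondrial genes
#'   (default uniform).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param library_meanlog,library_sdlog Log-normal parameters of per-cell
#'   library size.
#' @param donor_concentration Dirichlet concentration of the per-donor jitter
#'   on mixture weights (larger = less between-donor variation).
#' @param outlier_donor `NULL`, or a list with `donor` and `subtype_freq`: that
#'   donor's subtype frequency is overridden, planting a compositional outlier.
#' @param mito_prefix Symbol prefix identifying mitochondrial genes.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_experiment()], [default_fixture()]
#' @export
sim_config <- function(genes,
                       cell_types,
                       weights_control,
                       donors,
                       proportion_shift = NULL,
                       de_effects = NULL,
                       subtype = NULL,
                       mito_level = NULL,
                       mito_profile = NULL,
                       dispersion = 2,
                       library_meanlog = log(1500),
                       library_sdlog = 0.3,
                       donor_concentration = 100,
                       outlier_donor = NULL,
                       mito_prefix = "MT-",
                       seed = 1L) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) abort("gene symbols must be unique")
  mito_genes <- genes[startsWith(genes, mito_prefix)]
  other_genes <- setdiff(genes, mito_genes)
  type_names <- names(cell_types)
  if (is.null(type_names) || anyDuplicated(type_names)) {
    abort("cell_types must be a uniquely named list")
  }

  if (is.null(proportion_shift)) proportion_shift <- numeric(0)
  shift <- setNames(rep(1, length(type_names)), type_names)
  shift[names(proportion_shift)] <- proportion_shift

  if (is.null(mito_level)) mito_level <- numeric(0)
  mlev <- setNames(rep(0, length(type_names)), type_names)
  mlev[names(mito_level)] <- mito_level
  if (any(mlev < 0 | mlev >= 1)) abort("mito_level must be in [0, 1)")
  if (length(mito_genes) == 0 && any(mlev > 0)) {
    abort("mito_level > 0 but no genes carry the mitochondrial prefix")
  }
  if (is.null(mito_profile)) {
    mito_profile <- setNames(rep(1, length(mito_genes)), mito_genes)
  }

  donors <- as_tibble(donors)
  stopifnot(all(c("donor", "condition", "n_cells") %in% names(donors)))
  if (!all(donors$condition %in% c("control", "disease"))) {
    abort("donor condition must be 'control' or 'disease'")
  }
  if (any(donors$n_cells <= 0)) abort("n_cells must be positive")
  if (dispersion <= 0) abort("dispersion must be > 0")

  w <- setNames(rep(0, length(type_names)), type_names)
  w[names(weights_control)] <- weights_control
  if (any(w < 0) || sum(w) <= 0) abort("mixture weights must be non-negative, not all zero")

  for (tn in type_names) {
    prof <- cell_types[[tn]]$profile
    if (is.null(names(prof)) || !all(names(prof) %in% other_genes)) {
      abort("each profile must be named by non-mitochondrial genes")
    }
    if (any(prof < 0)) abort("profiles must be non-negative")
  }

  de_effects <- if (is.null(de_effects)) {
    tibble(cell_type = character(), gene = character(),
           condition = character(), beta = numeric())
  } else {
    as_tibble(de_effects)
  }
  if (nrow(de_effects)) {
    stopifnot(all(de_effects$gene %in% genes),
              all(de_effects$cell_type %in% type_names),
              all(de_effects$condition %in% c("control", "disease", "both")))
  }

  if (!is.null(subtype)) {
    stopifnot(subtype$parent %in% type_names)
    gating <- c(subtype$gene_a, subtype$gene_b)
    if (!all(gating %in% genes)) abort("subtype gating genes must be in the gene list")
    if (any(gating %in% mito_genes)) {
      abort("subtype gating genes must not be mitochondrial genes")
    }
    for (f in c(subtype$freq_control, subtype$freq_disease)) {
      if (f < 0 || f > 1) abort("subtype frequencies must be in [0, 1]")
    }
  }
  if (!is.null(outlier_donor)) {
    stopifnot(outlier_donor$donor %in% donors$donor)
  }

  structure(list(
    genes = genes, mito_genes = mito_genes, other_genes = other_genes,
    cell_types = cell_types, weights_control = w / sum(w),
    proportion_shift = shift, donors = donors, de_effects = de_effects,
    subtype = subtype, mito_level = mlev,
    mito_profile = mito_profile / sum(mito_profile),
    dispersion = dispersion, library_meanlog = library_meanlog,
    library_sdlog = library_sdlog, donor_concentration = donor_concentration,
    outlier_donor = outlier_donor, mito_prefix = mito_prefix,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d genes (%d mito), %d cell types, %d donors, %d planted effects%s\n",
    length(x$genes), length(x$mito_genes), length(x$cell_types),
    nrow(x$donors), nrow(x$de_effects),
    if (is.null(x$subtype)) "" else sprintf(", subtype '%s'", x$subtype$name)
  ))
  invisible(x)
}

# Full relative-expression profile over all genes for one (type, condition,
# subtype) stratum: mito share fixed at mito_level, DE effects applied
# multiplicatively without renormalization so the planted log2 effect is the
# generative log fold change.
stratum_profile <- function(config, type, condition, is_subtype) {
  prof <- config$cell_types[[type]]$profile
  full <- setNames(rep(0, length(config$genes)), config$genes)
  psum <- sum(prof)
  if (psum > 0) {
    full[names(prof)] <- prof / psum * (1 - config$mito_level[[type]])
  }
  if (length(config$mito_genes)) {
    full[names(config$mito_profile)] <-
      config$mito_profile * config$mito_level[[type]]
  }
  if (!is.null(config$subtype) && is_subtype) {
    full[c(config$subtype$gene_a, config$subtype$gene_b)] <- config$subtype$level
  }
  eff <- config$de_effects
  eff <- eff[eff$cell_type == type &
               (eff$condition == condition | eff$condition == "both"), , drop = FALSE]
  if (nrow(eff)) {
    full[eff$gene] <- full[eff$gene] * 2^eff$beta
  }
  full
}

#' Simulate a multi-donor two-condition experiment
#'
#' Draws one count matrix per donor from the generative model described in
#' [sim_config()], together with a per-cell table and a ground-truth ledger.
#' Output is deterministic for a fixed config (including its seed).
#'
#' @param config A [sim_config].
#' @return A list with elements:
#'   * `matrices`: named list of [count_matrix], one per donor;
#'   * `cells`: tibble with one row per cell (`barcode`, `sample_id`, `donor`,
#'     `condition`, `cluster` — the true type index, usable as upstream
#'     clustering labels —, `cell_type_true`, `is_subtype_true`);
#'   * `truth`: `sim_truth` list with the planted DE ledger, configured and
#'     realized per-donor type proportions, subtype spec, and outlier donor.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(config) {
  type_names <- names(config$cell_types)
  k <- length(type_names)
  base_w <- list(
    control = config$weights_control,
    disease = {
      wd <- config$weights_control * config$proportion_shift
      wd / sum(wd)
    }
  )

  matrices <- list()
  cell_rows <- list()
  weight_rows <- list()

  for (d in seq_len(nrow(config$donors))) {
    donor <- config$donors$donor[d]
    condition <- config$donors$condition[d]
    n <- config$donors$n_cells[d]

    w <- base_w[[condition]]
    jit <- rgamma(k, shape = config$donor_concentration * w, rate = 1)
    # degenerate gamma draws (all-zero) cannot occur for positive shapes, but
    # a zero-weight type yields shape 0 -> exactly 0, which is intended
    wj <- jit / sum(jit)
    types <- sample(type_names, n, replace = TRUE, prob = wj)

    freq <- 0
    if (!is.null(config$subtype)) {
      freq <- if (condition == "control") config$subtype$freq_control
              else config$subtype$freq_disease
      if (!is.null(config$outlier_donor) && donor == config$outlier_donor$donor) {
        freq <- config$outlier_donor$subtype_freq
      }
    }
    is_sub <- rep(FALSE, n)
    if (!is.null(config$subtype)) {
      parent <- types == config$subtype$parent
      is_sub[parent] <- rbinom(sum(parent), 1, freq) == 1
    }

    lib <- rlnorm(n, config$library_meanlog, config$library_sdlog)
    counts <- matrix(0L, nrow = length(config$genes), ncol = n,
                     dimnames = list(config$genes, NULL))
    # stratum order must be locale-independent (factor() sorts levels with
    # LC_COLLATE), or the RNG stream consumption would vary by environment
    stratum_levels <- c(outer(type_names, c(FALSE, TRUE), paste, sep = "."))
    strata <- factor(paste(types, is_sub, sep = "."),
                     levels = stratum_levels[stratum_levels %in%
                                               paste(types, is_sub, sep = ".")])
    for (s in levels(strata)) {
      idx <- which(strata == s)
      prof <- stratum_profile(config, types[idx[1]], condition, is_sub[idx[1]])
      mu <- outer(prof, lib[idx])
      counts[, idx] <- rnbinom(length(mu), mu = mu, size = config$dispersion)
    }
    bc <- sprintf("%s_%04d", donor, seq_len(n))
    colnames(counts) <- bc
    matrices[[donor]] <- count_matrix(counts, sample_id = donor)

    cell_rows[[donor]] <- tibble(
      barcode = bc, sample_id = donor, donor = donor, condition = condition,
      cluster = match(types, type_names), cell_type_true = types,
      is_subtype_true = is_sub
    )
    w_cfg <- unname(base_w[[condition]])
    weight_rows[[donor]] <- tibble(
      donor = donor, condition = condition, cell_type = type_names,
      weight_configured = w_cfg,
      weight_jittered = unname(wj),
      proportion_realized = as.numeric(table(factor(types, type_names)) / n)
    )
  }

  cells <- bind_rows(cell_rows)
  truth <- structure(list(
    planted = config$de_effects,
    weights = bind_rows(weight_rows),
    subtype = config$subtype,
    outlier_donor = if (is.null(config$outlier_donor)) NA_character_
                    else config$outlier_donor$donor,
    seed = config$seed
  ), class = "sim_truth")

  list(matrices = matrices, cells = cells, truth = truth)
}

#' Default small-experiment fixture
#'
#' A compact configuration exercising every pipeline stage: 300 genes (10
#' mitochondrial), five cell types including a cardiomyocyte-like type with
#' high mitochondrial content, four donors per condition with 400 cells each,
#' a 2x macrophage proportion shift in disease, 20 planted DE genes at
#' |log2 effect| between 1 and 2 in T cells, condition-specific and shared
#' transcription-factor effects, and a 7% TBX21+RUNX1+ subtype within disease
#' T cells. Runs the full pipeline in well under a minute.
#'
#' @param outlier If `TRUE`, one control donor ("ctrl4") is planted as a
#'   compositional outlier: it alone contains subtype cells among controls,
#'   mirroring a donor that Grubbs screening should remove.
#' @param seed Integer seed stored in the config.
#' @return A [sim_config].
#' @export
default_fixture <- function(outlier = FALSE, seed = 1L) {
  n_mito <- 10
  mito <- sprintf("MT-%d", seq_len(n_mito))
  gate <- c("TBX21", "RUNX1")
  type_names <- c("macrophage", "Tcell", "fibroblast", "endothelial", "cardiomyocyte")
  markers <- list(
    macrophage = c("MRC1", "CD68", "LYZ"),
    Tcell = c("CD3E", "CD3D", "IL7R"),
    fibroblast = c("DCN", "COL1A1", "PDGFRA"),
    endothelial = c("PECAM1", "VWF", "CDH5"),
    cardiomyocyte = c("TNNT2", "MYH7", "RYR2")
  )
  de_genes <- sprintf("DE%02d", 1:20)
  tf_genes <- c("TFD1", "TFD2", "TFB1", "TFB2")
  named <- c(gate, unlist(markers, use.names = FALSE), de_genes, tf_genes)
  n_generic <- 300 - n_mito - length(named)
  generic <- sprintf("G%03d", seq_len(n_generic))
  other <- c(named, generic)

  profiles <- withr::with_seed(1234L, {
    base <- setNames(rlnorm(length(generic), 0, 1), generic)
    lapply(type_names, function(tn) {
      prof <- setNames(rep(0, length(other)), other)
      prof[generic] <- base * rlnorm(length(generic), 0, 0.3)
      for (tn2 in type_names) {
        prof[markers[[tn2]]] <- if (tn2 == tn) 40 else 0.02
      }
      prof[de_genes] <- 1.5
      prof[tf_genes] <- 1.0
      prof[gate] <- 0
      prof
    })
  })
  names(profiles) <- type_names
  cell_types <- lapply(type_names, function(tn) {
    list(markers = markers[[tn]], profile = profiles[[tn]])
  })
  names(cell_types) <- type_names

  betas <- rep(c(1, -1, 1.5, -1.5, 2, -2), length.out = 20)
  de_effects <- bind_rows(
    tibble(cell_type = "Tcell", gene = de_genes, condition = "disease", beta = betas),
    tibble(cell_type = "Tcell", gene = c("TFD1", "TFD2"),
           condition = "disease", beta = 2),
    tibble(cell_type = "Tcell", gene = c("TFB1", "TFB2"),
           condition = "both", beta = 2)
  )

  donors <- tibble(
    donor = c(sprintf("ctrl%d", 1:4), sprintf("dis%d", 1:4)),
    condition = rep(c("control", "disease"), each = 4),
    n_cells = 400L
  )

  sim_config(
    genes = c(mito, other),
    cell_types = cell_types,
    weights_control = c(macrophage = 0.30, Tcell = 0.25, fibroblast = 0.20,
                        endothelial = 0.15, cardiomyocyte = 0.10),
    proportion_shift = c(macrophage = 2),
    donors = donors,
    de_effects = de_effects,
    subtype = list(
      name = "Th17.1", parent = "Tcell", gene_a = "TBX21", gene_b = "RUNX1",
      freq_control = 0, freq_disease = 0.07, level = 0.012
    ),
    mito_level = c(macrophage = 0.03, Tcell = 0.03, fibroblast = 0.03,
                   endothelial = 0.03, cardiomyocyte = 0.30),
    dispersion = 2,
    outlier_donor = if (outlier) list(donor = "ctrl4", subtype_freq = 0.04),
    seed = seed
  )
}

#' Strip all planted structure from a config
#'
#' Returns a copy with no DE effects, no proportion shift, no subtype, and no
#' outlier donor: a planted-null experiment for type-I error checks.
#'
#' @param config A [sim_config].
#' @param seed Optional replacement seed.
#' @return A [sim_config].
#' @export
as_null_config <- function(config, seed = config$seed) {
  config$de_effects <- config$de_effects[0, ]
  config$proportion_shift[] <- 1
  config$subtype <- NULL
  config$outlier_donor <- NULL
  config$seed <- as.integer(seed)
  config
}

#' Marker map matching [default_fixture()]
#' @return Named list of marker vectors, one per simulated cell type.
#' @export
default_marker_map <- function() {
  list(
    macrophage = c("MRC1", "CD68", "LYZ"),
    Tcell = c("CD3E", "CD3D", "IL7R"),
    fibroblast = c("DCN", "COL1A1", "PDGFRA"),
    endothelial = c("PECAM1", "VWF", "CDH5"),
    cardiomyocyte = c("TNNT2", "MYH7", "RYR2")
  )
}

#' Directed gene sets matching [default_fixture()]
#'
#' Three sets over the fixture's planted T-cell genes: all-upregulated,
#' all-downregulated, and a mixed set in which the downregulated genes are
#' declared repressors (so their inverted sign contributes positively).
#'
#' @return Named list of [directed_gene_set].
#' @export
default_gene_sets <- function() {
  betas <- rep(c(1, -1, 1.5, -1.5, 2, -2), length.out = 20)
  de_genes <- sprintf("DE%02d", 1:20)
  up <- de_genes[betas > 0]
  down <- de_genes[betas < 0]
  list(
    planted_up = directed_gene_set("planted_up", up),
    planted_down = directed_gene_set("planted_down", down),
    planted_mixed = directed_gene_set(
      "planted_mixed", c(up[1:4], down[1:4]),
      c(rep("activator", 4), rep("repressor", 4))
    )
  )
}

#' Transcription-factor catalog matching [default_fixture()]
#' @return Character vector of symbols: the gating genes, the planted
#'   disease-only and both-condition TFs, and a few unaffected genes.
#' @export
default_tf_catalog <- function() {
  c("TBX21", "RUNX1", "TFD1", "TFD2", "TFB1", "TFB2", "G001", "G002", "G003")
}
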