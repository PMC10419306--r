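# Shared fixtures and independent oracles, built in code at test time.

# dense matrix -> count_matrix with auto names
cm <- function(mat, sample_id = "s1", genes = NULL, barcodes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(mat)))
  if (is.null(barcodes)) barcodes <- sprintf("c%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, barcodes)
  count_matrix(mat, sample_id = sample_id)
}

# Exhaustive-enumeration oracle for the two-sided rank-sum p-value
# (tie-free instances): enumerate every assignment of pooled ranks to group a.
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  sums <- colSums(matrix(r[combos], nrow = na))
  min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
}

# Pairwise-counting oracle for the Mann-Whitney AUC (ties count 1/2).
pairwise_auc <- function(pos, neg) {
  wins <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(wins)
}

# Small 5-type config over few genes for composition replicates: profiles are
# generic expression only; composition depends on the mixture, not the genes.
mini_types_config <- function(shift = c(typeA = 2), seed = 1L,
                              n_cells = 400L, n_genes = 30L) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  type_names <- c("typeA", "typeB", "typeC", "typeD", "typeE")
  prof <- setNames(rep(1, n_genes), genes)
  cell_types <- lapply(type_names, function(tn) {
    list(markers = genes[1], profile = prof)
  })
  names(cell_types) <- type_names
  sim_config(
    genes = genes,
    cell_types = cell_types,
    weights_control = c(typeA = 0.30, typeB = 0.25, typeC = 0.20,
                        typeD = 0.15, typeE = 0.10),
    proportion_shift = shift,
    donors = tibble::tibble(
      donor = c(sprintf("c%d", 1:4), sprintf("d%d", 1:4)),
      condition = rep(c("control", "disease"), each = 4),
      n_cells = as.integer(n_cells)
    ),
    library_meanlog = log(200), library_sdlog = 0.3,
    seed = seed
  )
}

# Simulated default fixture shared across test files (computed once per run).
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(default_fixture())
    cache
  }
})

merged_fixture_counts <- function(sim = fixture_sim()) {
  mats <- lapply(sim$matrices, function(m) m$counts)
  count_matrix(do.call(cbind, unname(mats)), sample_id = "merged")
}
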