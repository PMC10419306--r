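test_that("identical seeds reproduce the experiment bitwise; seeds differ otherwise", {
  cfg <- mini_types_config(seed = 11)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(
    lapply(s1$matrices, function(m) m$counts),
    lapply(s2$matrices, function(m) m$counts)
  )
  expect_identical(s1$cells, s2$cells)
  s3 <- simulate_experiment(mini_types_config(seed = 12))
  expect_false(identical(s1$matrices[[1]]$counts, s3$matrices[[1]]$counts))
})

test_that("the planted null carries an empty ledger and no structure", {
  cfg <- as_null_config(default_fixture())
  expect_equal(nrow(cfg$de_effects), 0)
  expect_true(all(cfg$proportion_shift == 1))
  expect_null(cfg$subtype)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$truth$planted), 0)
  expect_false(any(sim$cells$is_subtype_true))
})

test_that("a planted log2 effect is recovered from group mean counts", {
  genes <- sprintf("g%02d", 1:20)
  prof <- setNames(rep(1, 20), genes)
  cfg <- sim_config(
    genes = genes,
    cell_types = list(typeA = list(markers = "g01", profile = prof)),
    weights_control = c(typeA = 1),
    donors = tibble::tibble(
      donor = c("c1", "d1"), condition = c("control", "disease"),
      n_cells = 500L
    ),
    de_effects = tibble::tibble(
      cell_type = "typeA", gene = "g05", condition = "disease", beta = 2
    ),
    library_meanlog = log(400), library_sdlog = 0.2,
    seed = 5
  )
  sim <- simulate_experiment(cfg)
  mc <- Matrix::rowMeans(sim$matrices$c1$counts)
  md <- Matrix::rowMeans(sim$matrices$d1$counts)
  expect_lt(abs(log2(md[["g05"]] / mc[["g05"]]) - 2), 0.3)
  # unplanted genes stay near ratio 0
  expect_lt(max(abs(log2(md[genes[-5]] / mc[genes[-5]]))), 0.3)
})

test_that("very large dispersion approaches Poisson (variance ~ mean)", {
  cfg <- mini_types_config(shift = NULL, seed = 3)
  cfg$dispersion <- 1e6
  cfg$library_sdlog <- 1e-8 # freeze library size so only count noise remains
  sim <- simulate_experiment(cfg)
  x <- as.matrix(sim$matrices[[1]]$counts)
  vm <- apply(x, 1, var) / rowMeans(x)
  expect_lt(abs(median(vm) - 1), 0.15)
})

test_that("realized type proportions concentrate around configured weights", {
  cfg <- mini_types_config(shift = NULL, seed = 9, n_cells = 4000L)
  cfg$donor_concentration <- 1e6 # suppress donor jitter for this check
  sim <- simulate_experiment(cfg)
  w <- sim$truth$weights
  expect_lt(max(abs(w$proportion_realized - w$weight_configured)), 0.03)
})

test_that("cell-type mitochondrial content follows the configured share", {
  sim <- fixture_sim()
  metrics <- dplyr::bind_rows(lapply(sim$matrices, compute_qc_metrics))
  joined <- dplyr::left_join(metrics, sim$cells, by = c("barcode", "sample_id"))
  means <- tapply(joined$pct_mito, joined$cell_type_true, mean)
  expect_gt(means[["cardiomyocyte"]], 25)
  expect_lt(max(means[setdiff(names(means), "cardiomyocyte")]), 6)
})

test_that("subtype cells co-express the gating genes; others nearly never do", {
  sim <- fixture_sim()
  counts <- merged_fixture_counts(sim)$counts
  gate <- coexpression_gate(counts, "TBX21", "RUNX1")
  sub <- sim$cells$barcode[sim$cells$is_subtype_true]
  non <- sim$cells$barcode[!sim$cells$is_subtype_true]
  expect_gt(mean(gate[sub]), 0.9)
  expect_equal(sum(gate[non]), 0)
})

test_that("config validation rejects contradictory settings", {
  cfg <- mini_types_config()
  expect_error(
    sim_config(
      genes = c("MT-1", "A", "B"),
      cell_types = list(t1 = list(markers = "A",
                                  profile = c(A = 1, B = 1))),
      weights_control = c(t1 = 1),
      donors = tibble::tibble(donor = "d", condition = "control", n_cells = 10L),
      subtype = list(name = "s", parent = "t1", gene_a = "MT-1", gene_b = "B",
                     freq_control = 0, freq_disease = 0.1, level = 0.01),
      mito_level = c(t1 = 0.1)
    ),
    "mitochondrial"
  )
  expect_error({
    bad <- mini_types_config()
    bad$donors$n_cells[1] <- 0L
    do.call(sim_config, bad[c("genes", "cell_types", "weights_control", "donors")])
  }, "positive")
})

test_that("the default fixture runs the full pipeline end to end", {
  out <- withr::local_tempdir()
  manifest <- run_pipeline(default_pipeline_config(), out, quiet = TRUE)
  expect_true(all(c("simulate", "qc", "annotate", "de", "ges", "tfs",
                    "composition") %in% manifest$stage))
  expect_true(file.exists(file.path(out, "composition_celltype.tsv")))
})
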