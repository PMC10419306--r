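metrics_row <- function(n_features, n_counts, pct_mito, barcode = "c") {
  tibble::tibble(barcode = barcode, sample_id = "s", n_features = n_features,
                 n_counts = n_counts, pct_mito = pct_mito)
}

test_that("per-cell metrics match hand arithmetic, with degenerate conventions", {
  m <- cm(matrix(c(3, 2, 5, 0, 0, 0), 3, 2),
          genes = c("geneA", "geneB", "MT-1"))
  qc <- compute_qc_metrics(m)
  expect_equal(qc$n_features, c(3L, 0L))
  expect_equal(qc$n_counts, c(10, 0))
  expect_equal(qc$pct_mito, c(50, 0)) # all-zero cell defined as 0

  no_mt <- cm(matrix(c(3, 2, 5, 1, 1, 1), 3, 2))
  expect_equal(compute_qc_metrics(no_mt)$pct_mito, c(0, 0))
})

test_that("threshold boundaries are kept; discard rules are strict", {
  # healthy-BAL style thresholds: nFeature in [1850, 7450], nCount <= 85000,
  # mito <= 12%
  t <- qc_thresholds(min_features = 1850, max_features = 7450,
                     max_counts = 85000, max_pct_mito = 12)
  mets <- dplyr::bind_rows(
    metrics_row(1850, 10000, 5, "boundary_low"),
    metrics_row(1849, 10000, 5, "below"),
    metrics_row(7450, 10000, 12, "boundary_high"),
    metrics_row(7451, 10000, 5, "above"),
    metrics_row(3000, 85000, 5, "count_boundary"),
    metrics_row(3000, 85001, 5, "count_above")
  )
  res <- apply_qc_thresholds(mets, t)
  expect_equal(res$keep,
               c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("unset thresholds keep every cell; single-rule violators are counted", {
  mets <- dplyr::bind_rows(lapply(1:10, function(i) {
    metrics_row(1000 + i, 5000, 5, sprintf("c%d", i))
  }))
  expect_true(all(apply_qc_thresholds(mets, qc_thresholds())$keep))

  # 10-cell fixture: 3 cells violating exactly one rule each -> 7 kept
  mets$n_features[1] <- 10     # below min
  mets$n_counts[2] <- 99999    # above max count
  mets$pct_mito[3] <- 50       # above mito cap
  t <- qc_thresholds(min_features = 500, max_features = 8000,
                     max_counts = 90000, max_pct_mito = 12)
  res <- apply_qc_thresholds(mets, t)
  expect_equal(sum(res$keep), 7)
  expect_equal(res$reason[1:3],
               c("n_features below minimum", "n_counts above maximum",
                 "pct_mito above maximum"))
})

test_that("deferred mitochondrial filtering exempts labelled cell types", {
  t <- qc_thresholds(max_pct_mito = 5, defer_mito = TRUE,
                     mito_exempt_labels = "cardiomyocyte")
  mets <- dplyr::bind_rows(
    metrics_row(1000, 5000, 40, "cm"),
    metrics_row(1000, 5000, 7, "fib"),
    metrics_row(1000, 5000, 5, "fib_boundary")
  )
  res <- deferred_mito_filter(mets, c("cardiomyocyte", "fibroblast", "fibroblast"), t)
  expect_equal(res$keep, c(TRUE, FALSE, TRUE))

  # empty exempt list reduces to plain mito thresholding
  t2 <- qc_thresholds(max_pct_mito = 5)
  res2 <- deferred_mito_filter(mets, rep("fibroblast", 3), t2)
  plain <- apply_qc_thresholds(mets, t2)
  expect_equal(res2$keep, plain$keep)

  expect_error(deferred_mito_filter(mets, c("a", NA, "b"), t), "label")
})

test_that("filtering is monotone under threshold relaxation", {
  mets <- withr::with_seed(42, dplyr::bind_rows(lapply(1:50, function(i) {
    metrics_row(sample(0:3000, 1), sample(0:9e4, 1), runif(1, 0, 40),
                sprintf("c%d", i))
  })))
  strict <- qc_thresholds(min_features = 500, max_features = 2500,
                          max_counts = 6e4, max_pct_mito = 10)
  relaxed <- qc_thresholds(min_features = 200, max_features = 2800,
                           max_counts = 8e4, max_pct_mito = 20)
  k1 <- apply_qc_thresholds(mets, strict)$keep
  k2 <- apply_qc_thresholds(mets, relaxed)$keep
  expect_true(all(k2[k1]))
})

test_that("two-pass filtering equals single-pass for non-exempt cells", {
  mets <- withr::with_seed(43, dplyr::bind_rows(lapply(1:40, function(i) {
    metrics_row(sample(0:3000, 1), sample(0:9e4, 1), runif(1, 0, 30),
                sprintf("c%d", i))
  })))
  single <- qc_thresholds(min_features = 300, max_counts = 8e4,
                          max_pct_mito = 12)
  deferred <- qc_thresholds(min_features = 300, max_counts = 8e4,
                            max_pct_mito = 12, defer_mito = TRUE)
  pass1 <- apply_qc_thresholds(mets, deferred)
  kept1 <- pass1[pass1$keep, ]
  pass2 <- deferred_mito_filter(kept1, rep("fibroblast", nrow(kept1)), deferred)
  two_pass_kept <- sort(pass2$barcode[pass2$keep])
  one_pass <- apply_qc_thresholds(mets, single)
  expect_equal(two_pass_kept, sort(one_pass$barcode[one_pass$keep]))
})

test_that("downsampling is a deterministic column subset", {
  m <- cm(withr::with_seed(1, matrix(rpois(200, 2), 10, 20)))
  expect_identical(downsample_cells(m, 50, seed = 1), m) # n >= current
  empty <- downsample_cells(m, 0, seed = 1)
  expect_equal(ncol(empty$counts), 0)
  expect_equal(genes(empty), genes(m))

  d1 <- downsample_cells(m, 7, seed = 10)
  d2 <- downsample_cells(m, 7, seed = 10)
  expect_identical(barcodes(d1), barcodes(d2))
  # per-cell columns are untouched
  expect_equal(as.matrix(d1$counts), as.matrix(m$counts)[, barcodes(d1)])
})
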