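test_that("proportion tables divide by the right denominator at each level", {
  cells <- tibble::tibble(
    barcode = sprintf("c%d", 1:100),
    donor = "d1", condition = "control",
    cell_type = rep(c("A", "B"), c(30, 70)),
    is_subtype = FALSE
  )
  pt <- proportion_table(cells)
  expect_equal(setNames(pt$proportion, pt$cell_type), c(A = 0.3, B = 0.7))

  # subtype within parent: 7 gated of 100 parent cells -> 0.07
  tcells <- tibble::tibble(
    barcode = sprintf("t%d", 1:120),
    donor = "d1", condition = "control",
    cell_type = rep(c("Tcell", "other"), c(100, 20)),
    is_subtype = rep(c(TRUE, FALSE, FALSE), c(7, 93, 20))
  )
  pt2 <- proportion_table(tcells, level = "subtype", parent = "Tcell",
                          subtype_name = "Th17.1")
  expect_equal(pt2$proportion[pt2$cell_type == "Th17.1"], 0.07)

  # donors without parent cells are excluded with a warning
  extra <- dplyr::bind_rows(tcells, tibble::tibble(
    barcode = "x1", donor = "d2", condition = "control",
    cell_type = "other", is_subtype = FALSE
  ))
  expect_warning(
    pt3 <- proportion_table(extra, level = "subtype", parent = "Tcell"),
    "d2"
  )
  expect_false("d2" %in% pt3$donor)
})

test_that("per-donor proportions sum to one at every level", {
  sim <- fixture_sim()
  cells <- sim$cells
  cells$cell_type <- cells$cell_type_true
  cells$is_subtype <- cells$is_subtype_true
  for (pt in list(
    proportion_table(cells),
    proportion_table(cells, level = "subtype", parent = "Tcell")
  )) {
    sums <- tapply(pt$proportion, pt$donor, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  # realized proportions equal the generator's recorded realizations exactly,
  # and track the jittered weights within multinomial sampling noise (each
  # donor-by-type count is Binomial(n, w), so 4.5 sigma bounds all 40 entries
  # with failure probability ~3e-4)
  pt <- proportion_table(cells)
  w <- sim$truth$weights
  joined <- dplyr::left_join(pt, w, by = c("donor", "condition", "cell_type"))
  expect_equal(joined$proportion, joined$proportion_realized)
  n_per_donor <- table(cells$donor)[joined$donor]
  sigma <- sqrt(joined$weight_jittered * (1 - joined$weight_jittered) /
                  as.numeric(n_per_donor))
  expect_true(all(abs(joined$proportion - joined$weight_jittered) <
                    4.5 * sigma))
})

test_that("the pooled t test matches hand arithmetic and declares degeneracies", {
  res <- student_t_test(c(0.10, 0.12, 0.11, 0.13), c(0.20, 0.22, 0.21, 0.23))
  expect_equal(res$t, -10.954, tolerance = 1e-4)
  expect_equal(res$p, 3.5e-5, tolerance = 0.05)
  expect_equal(res$df, 6)
  expect_equal(classify_tier(res$p), "*")
  # cross-check against the standard implementation
  ref <- stats::t.test(c(0.10, 0.12, 0.11, 0.13), c(0.20, 0.22, 0.21, 0.23),
                       var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  same <- student_t_test(c(0.1, 0.2), c(0.2, 0.1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  degen <- student_t_test(c(0.1, 0.1), c(0.3, 0.3))
  expect_equal(degen$p, 0)
  expect_equal(degen$flag, "zero variance")

  expect_error(student_t_test(0.1, c(0.2, 0.3)), "insufficient donors")

  # antisymmetry under group swap
  a <- c(0.1, 0.15, 0.12)
  b <- c(0.2, 0.18, 0.22)
  expect_equal(student_t_test(a, b)$t, -student_t_test(b, a)$t)
  expect_equal(student_t_test(a, b)$p, student_t_test(b, a)$p)
})

test_that("tiers follow the two-threshold rule", {
  expect_equal(classify_tier(c(0.04, 0.05, 0.07, 0.1, 0.5)),
               c("*", "‡", "‡", "n.s.", "n.s."))
  expect_error(classify_tier(1.5))
})

test_that("Grubbs flags the single extreme value against the t-derived critical value", {
  res <- grubbs_test(c(1, 1, 1, 10))
  expect_equal(res$outlier_index, 4L)
  expect_equal(res$G, 1.5) # the maximum attainable for n = 4
  expect_equal(res$critical, 1.481, tolerance = 1e-3)

  res2 <- grubbs_test(c(1, 2, 3))
  expect_true(is.na(res2$outlier_index))
  expect_equal(res2$G, 1)
  expect_equal(res2$critical, 1.1543, tolerance = 1e-4)

  expect_error(grubbs_test(rep(2, 5)), "zero-variance")
  expect_error(grubbs_test(c(1, 2)), "at least 3")
})

test_that("Grubbs critical values match the t-distribution closed form", {
  for (n in 3:30) {
    tcrit <- stats::qt(1 - 0.05 / (2 * n), df = n - 2)
    expected <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    expect_equal(grubbs_critical(n, 0.05), expected, tolerance = 1e-6)
  }
})

test_that("Grubbs decisions are invariant under affine transforms", {
  withr::with_seed(55, {
    for (i in 1:20) {
      x <- rnorm(sample(4:10, 1))
      a <- runif(1, 0.5, 3)
      b <- rnorm(1)
      r1 <- grubbs_test(x)
      r2 <- grubbs_test(a * x + b)
      expect_equal(r1$G, r2$G, tolerance = 1e-10)
      expect_equal(r1$outlier_index, r2$outlier_index)
    }
  })
})

test_that("the composition report screens outliers and skips unsupported comparisons", {
  # one control donor's single gated cell is the only nonzero control
  # proportion; Grubbs removes it and the comparison is then unsupported
  pt <- tibble::tibble(
    donor = c(sprintf("c%d", 1:4), sprintf("d%d", 1:4)),
    condition = rep(c("control", "disease"), each = 4),
    cell_type = "Th17.1",
    n_cells = c(0, 0, 0, 1, 6, 8, 7, 9),
    proportion = c(0, 0, 0, 0.01, 0.06, 0.08, 0.07, 0.09)
  )
  rep <- composition_report(pt)
  expect_equal(rep$removed_donors, "c4")
  expect_equal(rep$status, "insufficient donors")
  expect_true(is.na(rep$p))
  # without screening the test runs
  rep2 <- composition_report(pt, screen_outliers = FALSE)
  expect_equal(rep2$status, "ok")
  expect_equal(rep2$removed_donors, "")
})

test_that("a planted two-fold shift is called significant on the fixture", {
  sim <- fixture_sim()
  cells <- sim$cells
  cells$cell_type <- cells$cell_type_true
  rep <- composition_report(proportion_table(cells))
  mac <- rep[rep$cell_type == "macrophage", ]
  expect_equal(mac$tier, "*")
  expect_gt(mac$fold_change, 1.3)
})
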