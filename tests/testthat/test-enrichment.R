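de_table <- function(genes, fc, significant = TRUE) {
  tibble::tibble(
    gene = genes, log2_fc = fc, p_value = 0.001, p_adjusted = 0.001,
    pct_1 = 50, pct_2 = 50,
    significant = rep_len(significant, length(genes))
  )
}

test_that("direction adjustment inverts repressors and reports dropped genes", {
  de <- de_table(c("A", "B"), c(-0.5, -0.5))
  s <- directed_gene_set("S", c("A", "B", "C"),
                         c("activator", "repressor", "activator"))
  adj <- adjust_directions(de, s)
  expect_equal(adj$adjusted_log2_fc, c(-0.5, 0.5)) # activator kept, repressor flipped
  expect_equal(attr(adj, "dropped"), "C")

  none <- adjust_directions(de_table("X", 1), s)
  expect_equal(nrow(none), 0)
  expect_setequal(attr(none, "dropped"), c("A", "B", "C"))
})

test_that("GES worked examples match the formula by hand", {
  # single activator gene self-normalizes to +/-1
  expect_equal(ges(de_table("A", 0.8), directed_gene_set("S", "A"))$ges, 1)
  expect_equal(ges(de_table("A", -0.8), directed_gene_set("S", "A"))$ges, -1)

  # G identical positive activators attain the bound G
  g10 <- sprintf("g%d", 1:10)
  rec <- ges(de_table(g10, rep(0.7, 10)), directed_gene_set("S", g10))
  expect_equal(rec$ges, 10)
  expect_equal(rec$G_scored, 10)

  # mixed set with a repressor: {+1.0 act, -0.5 act, -0.5 rep, +0.25 act}
  de <- de_table(c("A", "B", "C", "D"), c(1.0, -0.5, -0.5, 0.25))
  s <- directed_gene_set("S", c("A", "B", "C", "D"),
                         c("activator", "activator", "repressor", "activator"))
  expect_equal(ges(de, s)$ges, 1.25)
})

test_that("GES failure modes raise the declared errors", {
  s <- directed_gene_set("S", c("A", "B"))
  expect_error(ges(de_table(c("A", "B"), c(1, 2), significant = FALSE), s),
               "empty gene set after filtering")
  expect_error(ges(de_table(c("A", "B"), c(0, 0)), s),
               "degenerate normalizer")
  expect_error(ges(de_table("X", 1), s), "empty gene set")
})

test_that("significant_only gates which genes enter the score", {
  de <- de_table(c("A", "B"), c(1, 10), significant = c(TRUE, FALSE))
  s <- directed_gene_set("S", c("A", "B"))
  expect_equal(ges(de, s)$ges, 1) # only A enters, self-normalized
  expect_equal(ges(de, s, significant_only = FALSE)$ges, 1.1)
})

test_that("GES properties hold on random fold-change vectors", {
  withr::with_seed(2024, {
    for (i in 1:200) {
      g <- sample(2:12, 1)
      genes <- sprintf("g%d", seq_len(g))
      fc <- round(rnorm(g), 3)
      fc[fc == 0] <- 0.001
      dirs <- sample(c("activator", "repressor"), g, replace = TRUE)
      s <- directed_gene_set("S", genes, dirs)
      de <- de_table(genes, fc)
      base <- ges(de, s)$ges

      # scale invariance
      c_pos <- runif(1, 0.1, 10)
      expect_equal(ges(de_table(genes, fc * c_pos), s)$ges, base,
                   tolerance = 1e-9)
      # sign equivariance
      expect_equal(ges(de_table(genes, -fc), s)$ges, -base, tolerance = 1e-9)
      # bound
      expect_lte(abs(base), g + 1e-9)
      # repressor involution: flipping one gene's direction twice is identity
      flip <- dirs
      j <- sample(g, 1)
      flip[j] <- setdiff(c("activator", "repressor"), flip[j])
      flip2 <- flip
      flip2[j] <- setdiff(c("activator", "repressor"), flip2[j])
      expect_equal(ges(de, directed_gene_set("S", genes, flip2))$ges, base)
    }
  })
})

test_that("the GES bound is attained exactly for common-sign unit contributions", {
  genes <- sprintf("g%d", 1:6)
  rec <- ges(de_table(genes, rep(-2, 6)), directed_gene_set("S", genes))
  expect_equal(rec$ges, -6)
  expect_true(all(abs(rec$contributions$contribution) == 1))
})

test_that("ges_table scores computable pairs and reports the rest", {
  expect_equal(nrow(ges_table(list(cmp = de_table("A", 1)), list())), 0)

  de_up <- de_table(sprintf("u%d", 1:5), runif(5, 0.5, 2))
  de_dn <- de_table(sprintf("u%d", 1:5), -runif(5, 0.5, 2))
  s <- directed_gene_set("S", sprintf("u%d", 1:5))
  dead <- directed_gene_set("dead", "absent_gene")
  tab <- ges_table(list(up = de_up, down = de_dn), list(s, dead))
  expect_equal(nrow(tab), 4)
  ok <- dplyr::filter(tab, status == "ok")
  expect_gt(ok$ges[ok$comparison == "up"], 0)
  expect_lt(ok$ges[ok$comparison == "down"], 0)
  expect_true(all(grepl("empty gene set", tab$status[tab$set == "dead"])))
})

test_that("planted up- and down-regulated sets score with the right sign end to end", {
  sim <- fixture_sim()
  norm <- log_normalize(merged_fixture_counts(sim))
  cells <- sim$cells[match(colnames(norm), sim$cells$barcode), ]
  tc <- cells[cells$cell_type_true == "Tcell", ]
  de <- find_markers(norm, cells,
                     tc$barcode[tc$condition == "disease"],
                     tc$barcode[tc$condition == "control"])
  tab <- ges_table(list(Tcell = de), default_gene_sets())
  scores <- setNames(tab$ges, tab$set)
  expect_gt(scores[["planted_up"]], 0)
  expect_lt(scores[["planted_down"]], 0)
  # the mixed set declares its downregulated genes repressors, so every
  # contribution points up
  expect_gt(scores[["planted_mixed"]], scores[["planted_up"]] / 2)
})
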