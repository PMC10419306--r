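Package: diffstate
Title: Two-Condition Single-Cell Differential State Analysis with Signed
    Gene Enrichment Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-condition single-cell and
    single-nucleus differential state analysis: per-cell quality control with
    deferred mitochondrial filtering, cell downsampling, marker-based cluster
    annotation, co-expression subtype gating with ROC marker validation,
    Wilcoxon rank-sum differential expression with Seurat-convention fold
    changes, a direction-aware max-normalized gene enrichment score (GES),
    condition-specific transcription factor detection, and per-donor cell
    composition testing with Grubbs outlier screening. Includes a
    negative-binomial multi-donor simulator with a ground-truth ledger so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
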