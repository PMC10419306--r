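---
title: "Methods: models, statistics, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(diffstate)
```

diffstate analyzes a two-condition (control vs disease), multi-donor
single-cell or single-nucleus RNA-seq experiment: quality control,
annotation, differential expression, signed gene-set enrichment,
condition-specific transcription-factor detection, and donor-level
composition testing. This vignette documents the statistical model behind
each stage, every default and why it was chosen, and the design decisions a
reader would otherwise have to reverse-engineer from the code.

## Data model

Counts are held in a `count_matrix`: a sparse genes-by-cells integer matrix
(the 10x orientation) plus a sample label. Readers and writers exist for
Matrix Market triplets (`read_mtx_triplet()` / `write_mtx_triplet()`),
GMT gene-set files with a `|rep` member suffix marking repressors
(`read_gene_sets()`), one-symbol-per-line TF catalogs, tab-separated sample
sheets, and marker maps. Gzipped inputs are accepted transparently. All
tabular results are tibbles; model-like objects provide `tidy()`,
`glance()`, and `autoplot()` methods.

## Quality control

`compute_qc_metrics()` reports, per cell, the number of detected genes
(`n_features`), total counts (`n_counts`), and the mitochondrial percentage
(`pct_mito`, genes with the `MT-` prefix). `apply_qc_thresholds()` discards
a cell only when a metric is *strictly* outside its bound, so a cell sitting
exactly on a threshold is kept; this makes published threshold values
reproducible without off-by-one ambiguity.

The mitochondrial cap can be **deferred** (`defer_mito = TRUE`): the first
pass applies only the feature and count rules, and `deferred_mito_filter()`
applies the mitochondrial cap after annotation, exempting listed cell types.
The motivation is physiological: cardiomyocytes legitimately carry very high
mitochondrial content, so a global cap applied before annotation would
silently delete them. Running the cap with no exempt labels after the first
pass keeps exactly the same cells as a single-pass filter, which is tested.

`downsample_cells()` takes a uniform random subset of columns under a fixed
seed, preserving column order, for balancing samples before comparison.

## Normalization and annotation

`log_normalize()` produces `log(1 + count * scale_factor / total)` per cell
with `scale_factor = 1e4`, the standard library-size normalization.
`annotate_clusters()` assigns each cluster the label whose marker genes have
the highest mean normalized expression in that cluster; ties go to the first
label in declaration order (and are messaged). Marker quality can be checked
with `marker_auc()`, the Mann–Whitney AUC: the probability that a random
in-type cell expresses the marker higher than a random out-of-type cell,
ties counting one half. It is computed from rank sums and equals exhaustive
pair counting exactly — e.g. positives {2,3,4} against negatives {1,2,3}
give (1 + 0.5) + (2 + 0.5) + 3 = 7 wins over 9 pairs, AUC 7/9. A perfectly
separating marker scores 1, a constant gene 0.5.

`coexpression_gate()` defines a subtype as the cells with nonzero (or
above-threshold) expression of *both* gating genes, e.g. TBX21⁺RUNX1⁺ cells
within T cells. Positivity at threshold 0 is invariant under
log-normalization, so the gate may be applied to counts or normalized data.

## Differential expression

`find_markers()` compares two cell groups per gene with the Wilcoxon
rank-sum test (`rank_sum_test()`):

* exact p-values via the U distribution when both groups have at most 8
  observations and there are no ties;
* otherwise the normal approximation with tie correction and continuity
  correction, matching `wilcox.test(exact = FALSE, correct = TRUE)`.

Fold changes follow the Seurat convention:
`log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))` on normalized data, with
pseudocount 1 so genes absent from one group remain finite. Multiple testing
uses Bonferroni by default (again matching the convention for per-cluster
marker tables; Benjamini–Hochberg is available). Optional prefilters
(`min_pct`, `min_abs_log2fc`) restrict the genes *tested*, and the Bonferroni
multiplier is the number of genes actually tested.

## Signed gene enrichment score (GES)

For a directed gene set with members $i = 1..G$ entering the score, let
$f_i$ be the gene's log2 fold change with the sign *inverted for
repressors*. The score is

$$\mathrm{GES} = \frac{\sum_{i} f_i}{\max_i |f_i|}.$$

Properties (all tested): a single gene scores ±1; $G$ genes with identical
fold change score ±$G$; $|\mathrm{GES}| \le G$; the score is invariant under
positive rescaling of fold changes and equivariant under global sign flips.
By default only genes significant in the differential table enter
(`significant_only = TRUE`), and the normalizer is the maximum over the
entering genes. Degenerate inputs raise errors rather than returning
numbers: an empty post-filter set ("empty gene set after filtering") and an
all-zero normalizer ("degenerate normalizer"). `ges_table()` scores every
comparison × set pair, recording per-pair errors in a `status` column
instead of failing the whole table.

## Condition-specific transcription factors

`condition_specific_tfs()` retains a gene when it (a) is in the TF catalog,
(b) is significantly differentially expressed in the disease contrast, and
(c) is *not* significant in the matching control contrast. A TF absent from
the control table (untested there) counts as not significant and is
retained, with `control_status = "untested"` so the distinction is visible.
`tf_specificity_by_type()` builds both contrasts per cell type as
cell-type-vs-rest *within* each condition.

## Composition testing

`proportion_table()` computes per-donor cell-type proportions; at the
subtype level the denominator is the parent population (gated plus
complement rows sum to one), and donors without parent cells are excluded
with a warning rather than silently producing 0/0.

Per cell type, `composition_report()` compares control vs disease
proportions with a pooled-variance Student t test (`student_t_test()`,
control minus disease). Zero pooled variance is flagged: equal means give
t = 0, p = 1; different means give p = 0 with a `"zero variance"` flag.
Significance tiers are `*` for p < 0.05, `‡` for 0.05 ≤ p < 0.1, `n.s.`
otherwise.

Before testing, each condition's donors are screened with the single-outlier
Grubbs test: $G = \max_i |x_i - \bar x| / s$ against the critical value
$\frac{n-1}{\sqrt n}\sqrt{t^2/(n - 2 + t^2)}$ with
$t = t_{1-\alpha/(2n),\,n-2}$, removing at most one donor per group. If a
group is left with fewer than two donors, or one group is all zeros (its
variance carries no information), the comparison is reported as
`"insufficient donors"` instead of fabricating a p-value. This mirrors the
practical situation of a rare subtype present in essentially no control
donors: after an outlier control donor is screened out, the honest answer is
that the design cannot support the test.

## The simulator

Because real accession-scale data cannot ship with a package, every claim is
validated on `simulate_experiment()`, a generative model with a ground-truth
ledger:

* **Mixtures.** Each donor draws cell types from condition-specific weights
  (disease weights are the control weights times a per-type
  `proportion_shift`, renormalized), jittered per donor with a Dirichlet
  perturbation (concentration 100, i.e. realistic between-donor variation of
  a few percentage points).
* **Counts.** Gene g in cell i of type t is negative binomial with mean
  `library_i * expression_{g,t} * 2^beta` and size `dispersion`; `beta` is
  nonzero only where the ledger plants an effect for that (gene, type,
  condition). Large `dispersion` approaches Poisson (tested via
  variance/mean). Library sizes are log-normal (meanlog `log(1500)`,
  sdlog 0.3 by default).
* **Mitochondrial content** is a per-type expected count share (e.g. 0.30
  for the cardiomyocyte-like type, 0.03 elsewhere), so the deferred QC rule
  has something real to protect.
* **Subtype.** An optional co-expressing subtype occupies a set frequency of
  its parent type (7% in disease, 0 in control by default) and expresses the
  two gating genes at relative level `level`.
* **Outlier donor.** Optionally one control donor gets a nonzero subtype
  frequency, planting exactly the situation Grubbs screening exists for.

`default_fixture()` is the standard instance: 300 genes (10 mitochondrial),
five cell types, 4+4 donors × 400 cells, a 2× macrophage shift, 20 planted
T-cell DE genes at |log2 effect| 1–2, two disease-only and two
both-condition TF effects, and the 7% gated subtype. It runs the full
pipeline in seconds; the problem sizes are the package's own choice,
balancing statistical resolution against test runtime.

Two generator defaults deserve comment:

* `dispersion` is the negative-binomial *size* parameter (not its inverse),
  matching `rnbinom(mu, size)`; documentation and tests pin this down since
  both conventions appear in the wild.
* the subtype gating-gene `level` default (0.012 in the fixture, mean ≈ 18
  counts per gated cell) keeps negative-binomial dropout of the gating genes
  below a few percent, so a nonzero-in-both-genes gate measures the planted
  frequency rather than the dropout rate. At much lower levels the gate's
  sensitivity, not the biology, dominates the recovered frequency.

Simulation is deterministic for a fixed config: the seed is stored in the
config, all draws run under `withr::with_seed()`, and internal orderings are
locale-independent (factor level construction never relies on
locale-collated sorting, which would otherwise change the RNG consumption
order between environments).

## Pipeline

`run_pipeline()` executes simulate/ingest → qc → annotate → de → ges → tfs →
composition, writing each stage's tables under an output directory and a
`manifest.tsv` with MD5 hashes. Stages can be run in subsets; a stage whose
inputs are neither in memory nor on disk raises an error naming the missing
upstream stage. Outputs contain no timestamps, so reruns with the same
configuration are byte-identical (tested). Configurations come from R
(`pipeline_config()`, `default_pipeline_config()`) or YAML
(`read_pipeline_config()`), and real data enters via a sample sheet of
Matrix Market triplets plus a cell-metadata table.

## Limitations

The simulator is a test harness, not a biological emulator: it has no
ambient RNA, doublets, batch effects, or gene–gene correlation beyond the
mixture structure, and planted fold changes are exact multiplicative
effects. The rank-sum test treats cells as independent (no donor
pseudobulking), which is anticonservative on real data with strong donor
effects; composition testing, by contrast, is donor-level. Grubbs screening
removes at most one outlier per group and assumes approximate normality of
per-donor proportions.
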