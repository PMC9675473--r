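---
title: "Methods: the nephromac analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nephromac analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephromac)
```

# Scope and data model

`nephromac` implements the bespoke computational stages of a combined
single-cell and Visium spatial analysis of kidney mononuclear phagocytes
(MNPs) in lupus nephritis: droplet-RNA-seq quality control and
median-target normalization, cluster-level doublet flagging from per-cell
doublet scores, gene-set recovery-AUC (AUCell-style) scoring, rank-sum
marker and group testing, cross-dataset cell-type similarity by ridge
logistic regression, and a spot-neighborhood colocalization statistic for
spatial prediction-score channels. Upstream steps with strong published
tooling — per-cell doublet-score computation, batch-corrected graph
construction, community detection, embedding, and label transfer — are
treated as inputs, not reimplemented.

Containers are deliberately light: an `expr_matrix` is a sparse
`dgCMatrix` (genes × cells) with unique identifiers and a `raw` /
`normalized` layer tag; annotations, gene sets and spatial spots are plain
data frames and lists. The package's interface contract is its text
formats (10x MTX trio, GMT, Visium tissue-positions CSV, TSV outputs) and
two invariants drive the design: write→read round-trips are the identity,
and readers never reorder identifiers. A thin S3 layer keeps both explicit
and cheap to verify; conversion to richer Bioconductor containers is a
one-liner for users who want it.

# Quality control and normalization

Cells are kept when the number of detected genes lies in
[`min_genes` = 200, `max_genes` = 2500] and the mitochondrial fraction is
strictly below `max_mito_frac` = 5%; genes are then kept when expressed in
at least `min_cells_per_gene` = 3 of the *surviving* cells. The gene
filter always runs after the cell filter, and filtering is idempotent.
Mitochondrial genes are matched by the case-insensitive prefix `mt-` by
default (mouse convention), overridable with an explicit list.

Normalization scales every cell so its total equals the median of the
pre-normalization cell totals. This preserves within-cell proportions and
the zero pattern exactly; all-zero cells are a hard error pointing at the
filter step.

Highly variable genes are selected on natural-log `log1p` values of the
normalized matrix (the natural log is the convention of the Python
workflow family this pipeline mirrors; log2 would only rescale the mean
bounds). Per gene we compute the mean and the dispersion (variance/mean),
assign genes to 20 equal-frequency mean bins by rank (ties to the lower
bin), and standardize the dispersion within each bin; a bin with undefined
or zero spread contributes normalized dispersion 0. Genes pass with mean
in [0.0125, 3] and normalized dispersion ≥ 0.5. With fewer than 20 genes
the selection falls back to a single bin with a warning.

# Cluster-level doublet flagging

Per-cell doublet scores (produced upstream by any detector) are summarized
as a median per (sub)cluster. Cluster medians are robust-standardized —
centered on their median, scaled by 1.4826 × MAD — and each cluster's
robust z is turned into a one-sided upper-tail p-value. The published
description ("a median … per subcluster", "median absolute deviation
scores", "a 1-tailed t test … with BH correction") does not pin down the
reference distribution, so the default is a Student t with
`n_clusters − 1` degrees of freedom, with the standard normal available
behind `tail = "normal"`; the t tail is the more conservative of the two.
BH-adjusted p `< 0.1` (strict) flags a cluster; member cells are then
marked as potential doublets. Flagged cells are *reported*, not dropped,
by default — the published account is ambiguous about whether removal
preceded its reported working-set size, and reporting keeps the decision
with the analyst.

Two caveats are worth stating plainly. First, cluster labels are an input:
the statistic is agnostic to how the subclustering was produced. Second,
the null calibration of this rule is only approximately nominal — the
ratio of one median to the MAD of ~10 medians is heavier-tailed than its
nominal t reference, so with 10 exchangeable clusters the probability of
at least one false flag is measured at roughly 0.17 rather than ≤ 0.1.
The package documents this honestly rather than recalibrating, because the
construction itself (median / MAD / one-tailed test / BH < 0.1) is the
method being implemented. Power is excellent: a planted cluster whose
scores come from the doublet distribution (Beta(8, 4) vs singlet
Beta(2, 20)) is flagged essentially always.

# Gene-set recovery scoring and group tests

`aucell_score` ranks genes within each cell by decreasing expression, ties
broken by ascending gene index (a deterministic deviation from randomized
tie-breaking, recorded in the output contract), and integrates the
recovery curve — the cumulative count of gene-set members met while
descending the ranking — over the top `top_frac` of the universe
(default 0.05, the published AUCell default; the source workflow does not
state its value). The area is normalized by the maximum achievable area
for the set size, so a fully recovered small set scores 1; the
window-area alternative sits behind `normalization = "window"`. Scores
depend only on ranks, hence are invariant to any monotone transform of a
cell's expression vector.

Group-mean enrichment tables average per-cell scores per group and min-max
scale along rows or columns to [0, 1]; a constant row carries no contrast
and maps to 0 by convention.

Marker genes use the two-sided Wilcoxon rank-sum test of each cluster
against all other cells, with the tie-corrected normal approximation (the
convention of large-scale single-cell marker scans), BH adjustment across
genes within each comparison, and a strict `p_adj < 0.05` gate with
positive enrichment for the reported top 5. Pairwise group tests
(`pairwise_group_test`) use `stats::wilcox.test` per unordered pair with a
Bonferroni multiplier equal to the number of pairs. A small-n exact path
(`rank_sum_test(..., exact = TRUE)`) is provided and verified against full
enumeration.

# Cell-type similarity by ridge logistic regression

`fit_similarity` trains an L2-regularized (alpha = 0) binomial model on
standardized reference expression, optionally restricted to a
tissue-specific gene list, with zero-variance genes dropped. The penalty
path is 100 log-spaced values spanning [λ_max·10⁻⁴, λ_max] with λ_max
taken from the null-model gradient (extended by the usual factor for the
ridge case). Each of `n_iterations` = 50 iterations draws a fresh
stratified 10-fold partition — the fold shuffle is the only stochastic
element of the stated procedure, so it is what the iterations randomize —
computes the cross-validated binomial deviance along the path, selects the
largest penalty within one standard error of the minimum (`lambda.1se`),
and refits on the full reference. The penalized fits are solved by
`glmnet`; the cross-validation loop, 1-SE selection and ensembling are the
package's own and are cross-checked against `cv.glmnet` in the tests.

`score_query` standardizes the query with its *own* per-gene statistics —
the source procedure standardizes "in both the training and test sets" —
with training-side statistics behind `query_standardization = "train"`;
ensemble genes absent from the query enter as 0 (the standardized mean).
The final score is the mean over iterations of the positive-class
probability, always in [0, 1], and converges to the training prevalence as
the penalty grows without bound.

# Spatial colocalization and glomerular composition

For two per-spot channels, `neighborhood_correlation` computes the Pearson
(optionally Spearman) correlation within every spot's k-nearest
neighborhood on array coordinates (k = 7 by default: the focal spot plus
6 neighbors, approximating the Visium hex ring; the source does not state
k). A neighborhood with a constant channel returns no value. Each spot
then averages the defined correlations over *all* neighborhoods that
contain it — the stronger reading of "overlapping neighborhoods", with the
own-neighborhood-only variant behind a flag — and non-positive averages
become missing: positive-only retention, rendered downstream as gray. The
missing state deliberately distinguishes "no available score /
anti-correlated" from a zero score; a tiny epsilon keeps exact-zero
averages (cancellation cases) on the purged side regardless of summation
order. Distance ties in the k-NN step break by ascending spot index, so
all spatial operations are deterministic.

Because neighborhoods overlap, a planted within-region correlation bleeds
one neighborhood-radius outward: spots just outside a correlated region
inherit partially-correlated neighborhoods and are retained more often
than deep-null spots (which are retained at the ~50% rate a symmetric null
implies). Interpret the margins of a colocalization map accordingly.

Glomerulus-containing spots are selected as those whose podocyte-signature
prediction score strictly exceeds the channel's 0.95 quantile (no absolute
threshold is published; an absolute mode is provided). Composition within
the selected spots renormalizes the listed subset channels to sum to 1 per
spot, drops all-zero spots with a reported count, and averages; the output
sums to 1 by construction.

# Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable without downloads, and
their defaults are fixed once:

* `simulate_cells`: negative-binomial counts (dispersion φ = 0.8,
  variance μ + φμ²) with per-gene baseline means Gamma-distributed around
  `nb_mean` = 0.3, mimicking the skew of droplet data; 5 clusters × 100
  cells with 10 disjoint marker genes each at fold change 4; doublets
  (5%) as the rounded mean of two random singlet profiles — the standard
  construction doublet detectors assume — with doublet scores Beta(8, 4)
  against singlet Beta(2, 20); mitochondrial fractions Beta(2, 60)
  (mean ≈ 3%, a realistic minority above the 5% cutoff) planted by sizing
  a dedicated `mt-*` block; two strains with one disease-enriched cluster
  (90/10 mixing); optional QC-violating outlier cells.
* `simulate_spatial`: a square lattice (Euclidean metric; the hex offset
  adds nothing to testing the statistic) carved into concentric regions
  sized like a kidney section — cortex ≈ 55%, medulla ≈ 30%, pelvis ≈ 15%,
  with 5% of spots converted to glomeruli inside the cortex. Channel pairs
  are drawn from a latent bivariate normal with the planted correlation
  inside their region, mapped to `0.5 + 0.15·z` and clamped to [0, 1];
  at that noise level clamping is rare, so the planted Pearson correlation
  survives within sampling error. The podocyte channel is Beta(20, 4) in
  glomeruli versus Beta(2, 20) elsewhere.

Real data differ in ways the generators do not model: ambient RNA,
batch-specific chemistry, spot-level cell mixtures, spatially smooth
expression gradients, and zero-inflated prediction scores. Passing tests
therefore demonstrate correctness of the statistics under the assumed
structure, not robustness to these artifacts.

# Numerical choices and problem sizes

Ties everywhere break by ascending index; seeds are threaded through
`withr::with_seed` so no function clobbers the caller's RNG state, and
identical configurations are byte-identical. Predicted probabilities are
clamped to [10⁻¹⁰, 1 − 10⁻¹⁰] inside the CV deviance. The test suite and
the acceptance script run at deliberately modest sizes — hundreds of cells
and genes, 20×20–30×30 grids, 100–500 replicates for operating
characteristics — chosen so the full suite completes in about a minute on
one core while leaving Monte-Carlo error well inside the asserted margins.

# Known limitations

* Cluster-level doublet flagging exceeds its nominal false-flag rate (see
  above); it ranks and gates clusters well but its p-values should be read
  as ordering devices, not calibrated probabilities.
* The similarity ensemble assumes two classes; one-vs-rest cascades are
  out of scope.
* The spatial statistic carries signal one neighborhood-radius beyond
  region borders by construction; it makes no significance claim about the
  resulting map.
* Gene identifiers match case-sensitively by exact string; no alias
  resolution is attempted.
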