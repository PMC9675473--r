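# nephromac

Single-cell and spatial transcriptomic analysis of kidney macrophages in
lupus nephritis: a tested R implementation of the bespoke computational
stages of the workflow — everything between the standard upstream tools
(cellranger, doublet detectors, clustering, label transfer) and the
biological readouts.

It is written for computational biologists who need these stages as
reusable, seeded, unit-tested functions rather than one-off notebook code:

* **QC and normalization** — cell filters (200–2,500 detected genes,
  mitochondrial fraction < 5%), gene filter (expressed in ≥ 3 surviving
  cells), normalization of every cell to the **median pre-normalization
  total**, and highly-variable-gene selection (mean in [0.0125, 3],
  bin-standardized dispersion ≥ 0.5 over 20 equal-frequency mean bins).
* **Cluster-level doublet flagging** — per subcluster *c* with median
  doublet score *m<sub>c</sub>*, the robust z
  *z<sub>c</sub>* = (*m<sub>c</sub>* − median *m*) / (1.4826 · MAD *m*)
  is tested one-sided against a t reference (df = K − 1) and BH-adjusted;
  clusters with adjusted *p* < 0.1 are flagged.
* **Gene-set recovery scoring (AUCell-style)** — per cell, the area under
  the recovery curve of a gene set over the top 5% of the expression
  ranking, normalized to [0, 1]; group-mean enrichment tables with 0–1
  min-max scaling.
* **Marker and group testing** — Wilcoxon rank-sum (tie-corrected normal
  approximation) of each cluster versus the rest with BH adjustment and a
  strict *p*(adj) < 0.05 gate; pairwise rank-sum group tests with
  Bonferroni correction; exact small-sample path included.
* **Cell-type similarity** — ridge (L2) logistic regression on
  standardized expression, 10-fold cross-validation with the 1-SE penalty
  rule (`lambda.1se`), final score averaged over 50 fold-reshuffled
  iterations.
* **Spatial colocalization** — Pearson correlation of two per-spot
  channels across overlapping k-nearest neighborhoods (k = 7) on Visium
  array coordinates, averaged over all neighborhoods containing each
  spot, with **positive-only retention** (non-positive or undefined
  scores become missing, the "gray" spots); podocyte-signature selection
  of glomerulus-containing spots and subset composition within them.
* **Synthetic data** — seeded generators for negative-binomial count
  matrices with planted markers, doublets, mitochondrial fractions and
  strain mixing, and for spot lattices with anatomical regions and
  planted channel correlations, so the whole pipeline is testable
  offline.

## Worked example

```r
library(nephromac)

sim  <- simulate_cells(cell_sim_config(seed = 42, n_genes = 2000,
                                       cells_per_cluster = 60,
                                       outlier_cells = list(n_low_genes = 10,
                                                            n_high_mito = 10)))
qc   <- compute_qc(sim$matrix)                     # n_genes, totals, mito_frac
filt <- filter_cells_genes(sim$matrix, qc, qc_params())
filt
#> <expr_matrix> 1815 genes x 247 cells, layer = raw, 95963 nonzero
norm <- normalize_to_median(filt)

flag_doublet_clusters(sim$annotations$doublet_score,
                      sim$annotations$true_cluster)
#>        cluster n_cells median_score robust_z  p_value p_adj_bh flagged
#> 1           c1      60       0.0796    0.355 3.66e-01 7.33e-01   FALSE
#> ...
#> 6      doublet      16       0.6921   68.472 1.86e-11 1.49e-10    TRUE
```

Of 336 simulated cells, 247 survive QC (the planted low-complexity and
high-mitochondrial outliers fall out), every post-normalization total
equals the median pre-normalization total, and the only cluster flagged
as doublet-enriched is the planted doublet cluster (median score 0.69
against ~0.07–0.09 for real clusters).

```r
mk <- gene_set("c1_signature",
               sim$marker_genes$gene[sim$marker_genes$cluster == "c1"])
sc <- aucell_score(norm, mk)
cl <- sim$annotations$true_cluster[match(cell_ids(norm),
                                         sim$annotations$cell_id)]
round(group_mean_enrichment(sc, cl)$mean, 3)
#>         score
#> c1      0.326
#> c2      0.050
#> ...
```

The cluster-1 marker signature scores 0.33 in cluster 1 and ~0.05–0.09
everywhere else — the signature localizes to its cluster.

```r
sp <- simulate_spatial(spatial_sim_config(seed = 42))   # rho = 0.8 in cortex
co <- neighborhood_correlation(sp, "sigA", "sigB")      # k = 7, Pearson
median(co$score[sp$spots$region == "cortex"], na.rm = TRUE)
#> [1] 0.744
```

With a correlation of 0.8 planted between the two channels inside the
cortex, the cortical spots carry a median colocalization score of 0.74
while most spots deep in the medulla/pelvis are purged by positive-only
retention (305 of 400 spots keep a score, concentrated in and around the
cortex).

A command-line wrapper over the same functions lives in
`inst/cli/nephromac.R`
(`Rscript nephromac.R simulate|qc|flag-doublets|score-genesets|similarity|spatial-corr|glom-composition|markers ...`).

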