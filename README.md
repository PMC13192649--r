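# starmaps

Sparse task-specific perturbation NMF for batch and region effects in
labelled single-cell expression data, with odds-ratio gene-set enrichment.

## The problem

Single-cell atlases of complex tissue are assembled from many dissections:
each cell carries a **batch** label (sample/individual) and a **region**
label (where it was dissected). Regional differences are not simple
per-gene shifts — they perturb the whole expression subspace — so standard
batch-correction models that assume gene-wise offsets either under-correct
or erase biology. At the same time, one often wants to ask where a gene set
(for example, a list of disease-associated risk genes) is over-expressed,
at the level of single cells, clusters, and regions.

`starmaps` addresses both. It is written for computational biologists
working with multi-region, multi-sample scRNA-seq (or any labelled
non-negative samples-by-features data) who need an interpretable
decomposition of shared versus condition-specific structure.

## The model

For each observed (batch *j*, region *r*) task with expression block
`X_jr` (cells × genes), the model is

```
X_jr ≈ W_jr (H + E_j + F_r)
```

* `H` (k × p, non-negative): factor space shared by all data;
* `E_j`, `F_r` (k × p, sparse): additive batch- and region-specific
  perturbations of the factor space;
* `W_jr` (n_jr × k): per-cell memberships, each row on the probability
  simplex (non-negative, sums to 1).

The fit minimizes

```
Σ_jr 1/(2 n_jr) ||X_jr − W_jr (H + E_j + F_r)||²_F
  + λ₁ Σ_j ||E_j||₁ + λ₂ Σ_r ||F_r||₁
```

subject to `H ≥ 0` and `H + E_j + F_r ≥ 0`, by alternating a
simplex-constrained least-squares pass on the memberships with exact
coordinate-descent passes (soft-thresholded for the perturbations), so the
objective is non-increasing at every pass. The embedding `W` can then be
clustered free of regional structure, while `F_r` itself quantifies how far
each region's expression subspace sits from the shared one.

Around the factorization the package provides:

* **mixing score** — cluster-size-weighted deviation of within-cluster
  region proportions from the global proportions (0 = perfectly mixed);
* **label-transfer accuracy** — repeated disjoint query/reference draws
  scored by a shared-nearest-neighbour kNN vote, to confirm biological
  signal survives correction;
* **subspace perturbation distance** — `||AAᵀ − BBᵀ||₂ / ||BBᵀ||₂` between
  factor matrices;
* **odds-ratio enrichment** — quantile-matched expression thresholding of
  reconstructed data, per-cell and per-cluster 2×2 tables
  (`OR = n11·n22 / n12·n21`), Fisher's exact test (or the normal
  approximation on log OR), Bonferroni correction across clusters, and
  per-region summaries of enriched-cell percentages;
* **synthetic data** — a generator that draws from exactly the model above
  (plus count noise, dropout, and planted gene-set effects) so every claim
  is testable against ground truth.

## Worked example

```r
library(starmaps)

# ground truth: 2 batches x 3 regions, 4 factors, 60 genes, sparse perturbations
truth   <- simulate_truth(M = 2, R = 3, k = 4, p = 60,
                          perturb_sparsity = 0.05, seed = 7)
dataset <- sample_expression(truth, n_per_task = 50, noise_sd = 0.05, seed = 1007)

fit <- starmaps_fit(dataset, k = 4, lambda = 1e-3, seed = 7)
glance(fit)
#> # A tibble: 1 x 8
#>       k lambda1 lambda2 n_iter objective converged batch_l1 region_l1
#>   <int>   <dbl>   <dbl>  <int>     <dbl> <lgl>        <dbl>     <dbl>
#> 1     4   0.001   0.001    200     0.462 FALSE         24.0      27.7

recovery_report(fit, truth, attr(dataset, "W_true"))[1:3]
#> $h_correlation
#> [1] 0.9590811
#> $f_support_precision
#> [1] 0.5535714
#> $f_support_recall
#> [1] 0.96875
```

The fitted shared factors correlate at 0.96 with the generating truth after
alignment, and 97% of the planted region-perturbation entries are
recovered. Clustering the membership embedding and scoring regional mixing
shows the effect of the region penalty:

```r
blocks <- split_by_task(dataset)
emb    <- embed_cells(fit, attr(blocks, "cell_index"))
cl     <- cluster_cells(build_knn_graph(emb, 15), resolution = 1, seed = 1)
mixing_score(cl$cluster, dataset$cells$region)
#> # A tibble: 3 x 2
#>   region  score
#>   <chr>   <dbl>
#> 1 region1 0.0444
#> 2 region2 0.0622
#> 3 region3 0.0378
```

Scores near zero mean regions are well mixed across clusters. Averaged over
ten simulated datasets (recomputed by `scripts/acceptance.R`), the mean
mixing score of the regularized fit is roughly half that of a fit with the
region perturbations suppressed (`lambda2 = Inf`). Enrichment of a gene set in clusters:

```r
recon <- do.call(rbind, reconstruct_expression(fit, "full"))
thr   <- expression_threshold(recon, as.matrix(dataset$matrix))
bin   <- binarize_expression(recon, thr)
per_group_enrichment(bin, cl$cluster, gene_set(truth$gene_ids[1:10]),
                     correction = "bonferroni")
```

returns one row per cluster with the 2×2 counts, odds ratio, raw and
Bonferroni-adjusted p-values, and the `enriched` flag (`OR > 1` and
adjusted `p ≤ 0.05`).

A thin command-line wrapper over the same functions ships in
`inst/cli/starmaps.R` with subcommands `simulate | fit | cluster | enrich |
evaluate | run`, plus `run_starmaps_pipeline()` for configuration-driven
end-to-end runs.

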