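---
title: "Model and methods behind starmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind starmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starmaps)
```

## The model and its assumptions

`starmaps` models labelled non-negative expression data as a non-negative
matrix factorization whose factor space is perturbed per condition. Cells
are grouped into tasks by their (batch $j$, region $r$) labels, and each
task block $X_{jr}$ (cells $\times$ genes) is decomposed as

$$X_{jr} \approx W_{jr}\,(H + E_j + F_r),$$

with the objective

$$\sum_{j,r} \frac{1}{2\,n_{jr}} \lVert X_{jr} - W_{jr}(H+E_j+F_r)\rVert_F^2
  \;+\; \lambda_1 \sum_j \lVert E_j\rVert_1
  \;+\; \lambda_2 \sum_r \lVert F_r\rVert_1,$$

subject to $H \ge 0$, $H + E_j + F_r \ge 0$, and every row of every
$W_{jr}$ on the probability simplex. The assumptions this encodes:

* **Shared biology dominates.** A single non-negative factor matrix $H$
  describes the expression programs common to all batches and regions.
* **Condition effects are subspace perturbations, not gene shifts.**
  $E_j$ and $F_r$ move whole factors; the L1 penalties make those moves
  sparse, so only a minority of (factor, gene) coordinates are
  condition-specific. $E_j$ and $F_r$ may contain negative entries —
  regions can suppress genes — only the sums $H+E_j+F_r$ must stay
  non-negative.
* **Memberships are compositions.** The simplex rows of $W$ make each cell
  a mixture over $k$ programs, removing the per-cell scale freedom of
  plain NMF; per-cell depth must therefore be handled by normalization
  beforehand.
* The $1/n_{jr}$ weights keep small tasks from being swamped by large
  ones.

## Optimization and numerical choices

The fit alternates four passes, each of which cannot increase the
objective:

1. **Memberships.** Each row of $W_{jr}$ solves a simplex-constrained
   least-squares problem. All rows of a task share the $k \times k$ Gram
   matrix of $H+E_j+F_r$, so for $k \le 8$ the quadratic program is solved
   exactly by enumerating the $2^k - 1$ possible supports and keeping each
   row's best feasible candidate — a vectorized, exact step. For larger
   $k$ a projected-gradient descent with step $1/L$ ($L$ the Gram's
   largest eigenvalue) is used; it is monotone by construction. A final
   guard keeps a row's previous value wherever a candidate would not
   improve it, so the pass is monotone even under floating-point ties.
2. **Shared factor.** Exact cyclic coordinate descent on $H$. Coordinates
   in one factor row do not interact, so each row updates jointly across
   genes; the update clips against both $H \ge 0$ and the tightest
   $H + E_j + F_r \ge 0$ bound with the other blocks held fixed.
3. **Batch perturbations** and 4. **region perturbations.** Exact
   coordinate minimization with an L1 term: a soft-threshold at
   $\lambda_1$ (or $\lambda_2$) followed by the same feasibility clip.
   Because each coordinate step is an exact minimization of a convex
   one-dimensional function from a feasible point, descent is preserved.

Residual matrices are recomputed fresh at every pass boundary so that
incremental updates cannot drift. The objective is recorded after every
pass (`pass_trace`) and every outer iteration (`objective_trace`); the
test suite asserts non-increase of the pass trace to a $10^{-9}$ relative
slack.

**Initialization** runs the same machinery with the perturbations pinned
at zero: an NNDSVD-type seeding (positive parts of the leading singular
triplets of the stacked blocks) followed by alternating exact passes on
$W$ and $H$. The simplex projection of the seeded $W$ loses a per-row
scale; the mean pre-projection row sum is folded into $H$, and the first
$H$ pass refits the scale exactly. Initialization is deterministic; the
seed only perturbs degenerate all-zero singular blocks.

**Convergence** is declared when the relative objective change per outer
iteration falls below `tol` ($10^{-5}$ by default) or after `max_iter`
(200) iterations. On the L1 path the objective keeps creeping for a long
time, so runs at the default tolerance often use all 200 iterations; the
factors stabilize much earlier, which is why several tests and the
acceptance script use 60 iterations for fit-quality comparisons and 8 for
pure descent checks.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | — | latent factors; not selected automatically, choose by domain knowledge |
| `lambda` (`lambda1`, `lambda2`) | $10^{-3}$ | L1 weight on batch / region perturbations; `Inf` pins a perturbation family at zero; $\lambda \in \{0, 10^{-3}, 10^{-2}\}$ spans the useful range on normalized data |
| `tol`, `max_iter` | $10^{-5}$, 200 | outer convergence |
| `target_sum` | $10^4$ | per-cell library size before `log1p` |
| `frac` | 0.25 | a gene is "expressed in a group" when expressed in strictly more than this fraction of its cells |
| `alpha` | 0.05 | enrichment significance level (`OR > 1` and $p \le \alpha$) |
| `n_neighbors` | 20 | kNN size for the SNN graph and label transfer |
| `stability_floor` | 0.8 | minimum bootstrap-ARI stability when selecting a clustering resolution |

Normalization is library-size scaling, `log1p`, then per-gene division by
the standard deviation *without centering*: centering would break the
non-negativity the factorization requires. Scaling is per dataset; whether
to scale globally across datasets is exposed to the caller by normalizing
before or after merging.

## Design choices where the design was open

* **Penalty assignment.** Batch and region penalties are independent
  (`lambda1`, `lambda2`) but a single `lambda` argument sets both, which
  is the common operating mode.
* **Mixing score weighting.** The score is
  $\sum_k (n_k/n)\,\lvert q_{r,k} - \bar q_r\rvert$ with $q_{r,k}$ the
  within-cluster region proportion and $\bar q_r$ the global proportion —
  zero exactly when every cluster has the same regional composition.
  Cluster-size weighting is the default because it makes the score a
  population-level total-variation-style quantity; a uniform $1/K$
  weighting ships behind `weights = "uniform"` for comparison.
* **Subspace distance operands.** The normalized Gram distance
  $\lVert AA^\top - BB^\top\rVert_2 / \lVert BB^\top\rVert_2$ is applied
  to the $k \times p$ factor matrices ($H+E_j$ or $H+F_r$ against $H$):
  this is computable at any data size and measures exactly the quantity
  the perturbations act on.
* **Enrichment p-values.** Both Fisher's exact test (default) and the
  Wald/Woolf normal approximation on $\log \mathrm{OR}$ are implemented;
  the Haldane–Anscombe $+0.5$ correction is applied to all four cells
  whenever any cell is zero, which also makes the odds ratio defined for
  degenerate cells. On tables with all cells $\ge 20$ the two methods
  agree on significance at $\alpha = 0.05$ in the large majority of random
  tables; the exact test is preferred for the small counts that arise per
  cell. The group-level "expressed" rule is strictly greater than 25%.
* **Expression threshold.** $\mu$ is the quantile of the reconstructed
  entries at the raw zero fraction, with ties resolved by scanning the
  adjacent candidate cut and keeping the count mismatch minimal. Ties can
  make the target count unattainable; the mismatch is reported alongside
  $\mu$.
* **Which reconstruction feeds enrichment.** Both the cell-level
  reconstruction $W_{jr}(H+E_j+F_r)$ (`"full"`) and the corrected variants
  are exposed; the pipeline defaults to `"full"`, matching the idea that
  the threshold should reproduce the observed sparsity of the raw counts.
* **Multi-resolution clustering.** Tree-based multi-resolution
  reconciliation is deliberately *not* reimplemented; `select_resolution`
  is a clearly named stability stand-in: bootstrap subsample, recluster,
  score mean pairwise ARI on shared cells, and take the highest resolution
  above the stability floor. Raising the floor can only coarsen the
  choice.
* **Anchor genes.** A dispersion (variance/mean) ranking aggregated across
  datasets by best rank (then mean rank, then identifier) stands in for
  external anchor-selection tools; anchors are an input to the model, not
  part of it.
* **Serialization.** Models are written as a directory of plain TSV
  matrices plus a JSON attribute file (layout `H`, `E/<batch>`,
  `F/<region>`, `W/<task>`). Text at 17 significant digits round-trips
  the factors exactly; the objective traces pass through JSON and
  round-trip to $\sim 10^{-14}$ relative.

## What the synthetic generator does and does not emulate

`simulate_truth()` + `sample_expression()` draw from exactly the model the
fit assumes: gamma-distributed $H$ (mean 1), Bernoulli(0.05) perturbation
supports with signed gamma magnitudes, negative entries rescaled only at
infeasible coordinates so that $H + E_j + F_r \ge 0$, Dirichlet
memberships concentrated on one archetype per cell, and either a
Gaussian-noise surface clipped at zero (the normalized-scale view) or
Poisson counts with Bernoulli dropout (the raw view).
`plant_gene_set()` multiplies set-gene expression in chosen groups for
enrichment power tests.

Defaults ($M = 2$ batches, $R = 3$ regions, $k = 4$, $p = 60$ genes, 50
cells per task, noise SD 0.05, $\lambda = 10^{-3}$) are the conditions all
recovery and regularization tests run under; they are deliberately small
enough that a fit takes seconds. What the generator does **not** emulate:
real depth profiles and gene counts, hierarchical cell-type structure,
batch-to-batch library composition shifts, or correlated gene modules
beyond the $k$ factors. Passing tests therefore demonstrate correctness of
the algorithms under the model's own assumptions — parameter recovery,
calibration, monotonicity — not that the model captures everything in a
real atlas.

## Degenerate inputs and edge behavior

Zero-count cells are dropped with a warning at normalization.
Zero-variance genes are left unscaled. A cell expressing no genes yields a
Haldane-corrected odds ratio and is never flagged enriched. An all-zero
raw matrix gives $\mu = +\infty$ with a warning. A degenerate (constant)
embedding yields a complete graph with a warning. Label-transfer query
classes absent from the reference are counted as errors and logged. An
unused factor (zero membership mass) keeps its current $H$ row; unused
perturbation rows shrink toward zero.

## Known limitations

* The objective is non-convex; the fit finds a local optimum whose quality
  depends on the NNDSVD seeding. No restarts are performed.
* NMF identifiability is only up to factor permutation and positive
  scaling; all recovery metrics align factors first (exhaustive
  permutation for $k \le 8$, greedy beyond).
* The exact membership QP enumerates $2^k-1$ supports and is intended for
  the small $k$ regime typical of interpretable factorizations; larger
  $k$ falls back to slower projected gradients.
* Per-iteration cost is linear in cells and genes, but the implementation
  is in-memory and dense per task; atlases of $10^5$+ cells should be
  subsampled (`subsample_cells()`) as is done in the motivating analyses.
* `half_sd` in the transfer report is half the standard deviation across
  repeats — a conservative spread summary, not a standard error.
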