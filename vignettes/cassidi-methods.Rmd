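---
title: "Cluster similarity scoring and distinction-index ranking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster similarity scoring and distinction-index ranking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassidi)
```

# The model

`cassidi` compares two single-cell RNA-seq datasets that were clustered
*independently*. The central assumption is that if two clusters — one from
each dataset — represent the same cell type or state, their positive
marker genes will largely coincide, and genes that mark many clusters are
less informative about identity than genes that mark few. Negative markers
(genes under-expressed in a cluster) are ignored throughout: they tend to
be redundant across clusters and say little about identity.

## Cluster similarity score

For clusters 1 and 2 with retained marker sets $M_1$, $M_2$, write
$C_{12} = |M_1 \cap M_2|$, $U_1 = |M_1 \setminus M_2|$,
$U_2 = |M_2 \setminus M_1|$. The basic score is the Jaccard index
$\mathrm{CSS}_{basic} = C_{12} / (C_{12} + U_1 + U_2)$.

The enhanced score weights each gene. Marker detection supplies, per gene
and cluster, the natural-log fold change of average expression against the
background (`avg_logFC`), and the expressing fractions in cluster
(`pct.1`) and background (`pct.2`). The weight of gene $i$ in cluster 1 is

$$w_{i1} = \mathrm{avgLogFC}_{i1} \cdot \frac{\mathrm{pct1}_{i1}^2}{\mathrm{pct2}_{i1}},$$

large for genes that are strongly, widely and specifically expressed. The
uniqueness score of gene $i$ is $u_i = 1 - \sqrt{L_i / L_n}$, where $L_i$
is the number of clusters — across *both* datasets of the current run —
for which the gene is a retained marker and $L_n = m + n$ is the total
cluster count. $u_i$ is computed per parameter pair, over the clusters of
that run only, so a gene's uniqueness adapts to the granularity being
evaluated. The enhanced score is

$$\mathrm{CSS}_{enh} =
  \frac{\sum_{i \in C_{12}} (w_{i1} + w_{i2})\, u_i}
  {\sum_{i \in C_{12}} (w_{i1} + w_{i2})\, u_i
   + \sum_{j \in U_1} w_{j1} u_j + \sum_{k \in U_2} w_{k2} u_k} \in [0, 1].$$

When all weights and uniqueness scores are equal it reduces exactly to
$2C_{12} / (2C_{12} + U_1 + U_2)$, a doubly-counted Jaccard; the test
suite asserts this closed form.

## Distinction index

For an $m \times n$ matrix of CSS values, each row's (column's)
distinction index is its maximum minus the mean of its remaining entries.
A row with one strong partner and weak alternatives scores near 1; a row
with uniformly similar entries — ambiguous matching, typically
over-clustering — scores near 0. The matrix-level DI averages the $m + n$
row and column indices. Ranking parameter pairs by matrix DI therefore
prefers conditions that reveal crisp one-to-one correspondences while
keeping unmatched, condition-exclusive clusters cleanly isolated.

Two normalizations of the same sum are implemented because they genuinely
disagree whenever $m + n \neq mn$: dividing by $m + n$ (the default; the
mean of the indices actually computed) or by $mn$. For a square $k \times
k$ permutation-patterned 0/1 matrix the first gives 1 for every $k$, the
second $2/k$; both are exposed, and the ranking can differ between them,
so the choice is an explicit argument.

# Tunable parameters

| parameter | default | role |
|---|---|---|
| `res` | grid `0.4:2.0:0.2` | community-detection resolution; more clusters as it grows |
| `npcs` | grid `10:75:5` | principal components fed to the neighbor graph |
| `target_sum` | 10,000 | per-cell normalization total (counts scale) |
| `n_hvgs` | 2,000 | highly variable genes retained |
| `scale_cap` | 10 | upper cap on per-gene z-scores |
| `k` | 20 | neighbors in the SNN graph |
| `min_pct` | 0.1 | minimum expressing fraction for a gene to be tested |
| `min_logfc` | 0.25 | minimum natural-log fold change to be tested |
| `p_threshold` | 0.05 | adjusted-p retention cutoff for markers |
| `pct_floor` | 0.001 | floor on `pct.2` in the weight denominator |

The preprocessing defaults are the v3-era conventions of the standard
single-cell toolchain; all are arguments, none is hard-coded. The default
grid enumerates 9 × 14 = 126 parameter pairs; a third axis multiplies the
cell count accordingly (a 10-value axis gives 1,260 cells). Grid axes are
generated by integer index arithmetic (`start + k*step`) with an inclusive
`1e-9` end tolerance so the endpoint (e.g. `res = 2.0`) is never lost to
floating-point drift.

The marker test is a two-sided Wilcoxon rank-sum per gene (cluster versus
all other cells of the same dataset), normal approximation with tie and
continuity correction, Benjamini–Hochberg adjusted across the genes
actually tested. It is implemented vectorized — the per-gene rank and tie
tables are computed once per dataset and reused by every cluster — because
a grid sweep performs this test thousands of times; the test suite checks
its p-values against `stats::wilcox.test` to 1e-9.

# Numerical choices and degenerate inputs

* **`pct.2 = 0`**: exported marker tables legitimately contain markers
  absent from the background; the weight divides by
  `max(pct.2, pct_floor)` with `pct_floor = 0.001`, matching the 3-decimal
  granularity of the table dialect.
* **0/0 conventions**: two empty marker sets, or a run in which every
  marker has zero uniqueness, yield CSS 0 — "most dissimilar" is the
  conservative reading of the score's anchoring.
* **Clusters without retained markers** still count toward $L_n$ and
  produce a zero row/column plus a warning, rather than silently vanishing
  from the matrix.
* **Length-1 rows/columns**: "mean of the remaining entries" is undefined,
  and is taken as 0, so the DI is the single entry itself; this is the one
  case where the DI is not shift-invariant, and it is messaged.
* **Ties in the ranking** are broken toward fewer total clusters (the
  anti-over-clustering reading of the method's intent), then lower `res`,
  then lower `npcs` — a declared convention, deterministic under
  re-execution.
* **Determinism**: every stochastic step (truncated PCA initialisation,
  community detection) runs under a seed derived deterministically from
  `(base seed, res, npcs)`, so grid cells are independent and reproducible
  bit-for-bit across process restarts.
* **Natural-log dialect**: the weight formula presumes natural-log fold
  changes; tables carrying an `avg_log2FC` column are rejected with an
  explicit message rather than silently rescaled.

# The synthetic generator

`simulatePairedDatasets()` draws counts from a negative binomial with
gene-shared dispersion: background genes at mean `baseline_mean = 0.2`
everywhere, each cluster's own markers at `baseline_mean * fold_change` in
that cluster only, `dispersion = 0.5` (`size = 2`), and a log-normal
per-cell library-size jitter (`sdlog = 0.1`) so normalization is
non-trivial. The defaults — 4 shared clusters plus 1 knockout-exclusive
cluster, 200 cells per cluster, 1,000 genes, 25 disjoint markers per
cluster, fold change 8 — emulate the genotype-paired setting the method is
built for: two datasets with mostly one-to-one cluster structure plus one
stand-alone population. The baseline of 0.2 gives background expressing
fractions near 0.17 and marker in-cluster fractions near 0.7, sparse
levels typical of droplet data. Marker sets are disjoint across clusters
so the planted uniqueness is analytic ($L_i = 2$ for shared-cluster
markers, 1 for exclusive ones).

What the generator does *not* emulate: doublets, ambient RNA, batch
effects, correlated gene programs, continuous trajectories. Passing the
planted-recovery tests therefore shows the machinery is correct on clean
separable populations, not that clustering of real tissue is easy; on real
data the method's value is in the *ranking* across parameter pairs, which
only requires the DI to order conditions sensibly, not any condition to be
perfect.

# Design decisions made where the design was open

* **Default DI normalization** is the mean over the $m + n$ computed
  indices; the $1/(mn)$ variant is selectable. They coincide only when
  $m + n = mn$ (e.g. 2 × 2).
* **Louvain modularity on a Jaccard-weighted SNN graph** is the default
  community-detection backend. At high resolution it over-splits even
  cleanly separable data (our two-population fixture splits into 12
  clusters at `res = 2.0`); that is not a defect the package hides — it is
  precisely the behavior the DI ranking demotes, and the CSS/DI layers
  consume marker tables directly so any backend can be substituted.
* **Nebula "top" genes are ranked by the marker weight $w$** — the only
  ranking-compatible scalar the score framework defines; shared genes by
  the mean of their two weights. Display order: cluster-A-specific genes
  by decreasing A diamond, B-specific by increasing B diamond, shared
  genes center-out by mean diamond (best at the center, then alternating
  right, left, ...). Diamonds are `log1p` of the mean de-logged normalized
  expression — the same averaging convention the marker fold change uses.
* **Backgrounds** everywhere (markers, Nebula violins) are all cells of
  the same dataset outside the focal cluster.

# Problem sizes

The test suite and the acceptance script run the full pipeline on the
default simulated pair (1,800 cells, 1,000 genes) over a 3 × 3 grid —
`res` {0.4, 0.8, 1.2} × `nPCs` {10, 15, 20}, the low corner of the default
search space, appropriate to a 1,000-gene simulation — across five seeds; property
suites use 1,000 random fixtures per invariant. These sizes keep a
complete run in tens of seconds on one CPU while exercising every code
path; nothing in the method is specific to them.

# Known limitations

* Grid search only: optima between or outside grid points are
  approximated, never found.
* The DI can *hint* at graded cluster relationships but is not a
  trajectory method and should not be read as one.
* The framework ranks clusterings; it does not produce them. Its output
  quality is bounded by the clustering backend's suitability for the data.
* CSS is marker-based: clusters distinguished only by genes that fail the
  retention filter (low fold change, low prevalence) are invisible to it.
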