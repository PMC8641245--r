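---
title: "Inferring cell-specific miRNA-mRNA regulatory networks"
author: "scMiRNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-specific miRNA-mRNA regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMiRNet)
```

## The problem

Matched single-cell miRNA-mRNA co-sequencing (e.g. half-cell protocols,
where one cell's lysate is split and sequenced separately for small and
long RNA) yields paired expression profiles per cell, but such datasets
are small — typically a few dozen cells. Bulk association methods return
one network for the whole population and cannot say *in which cell* a
miRNA is actively repressing a target. scMiRNet infers one bipartite
miRNA-mRNA network per individual cell, restricted to putative binding
pairs from a sequence-based prior (e.g. a TargetScan export), and then
analyses the collection of per-cell networks: hub miRNAs, conserved and
rewired regulation, cell-cell similarity, clustering, crosstalk and
biclique modules.

## The per-cell association statistic

For a miRNA $r$ and an mRNA $t$, consider the scatter of all $n$ cells in
the $(x, y)$ plane of their expression values, and a focal cell $k$ at
$(x_k, y_k)$. Draw a box (a value window) around $x_k$ on the miRNA axis
containing $n_r^{(k)}$ cells, a box around $y_k$ on the mRNA axis with
$n_t^{(k)}$ cells, and let $n_{rt}^{(k)}$ count cells in both. The
statistic is

$$\rho_{rt}^{(k)} = \frac{n_{rt}^{(k)}}{n}
  - \frac{n_r^{(k)}}{n}\cdot\frac{n_t^{(k)}}{n},$$

the difference between the empirical joint neighborhood probability and
the product of the marginals. Under independence $\rho \approx 0$;
normalizing gives

$$z_{rt}^{(k)} = \frac{\sqrt{n-1}\,\bigl(n\,n_{rt}^{(k)} -
  n_r^{(k)} n_t^{(k)}\bigr)}{\sqrt{n_r^{(k)} n_t^{(k)}
  (n - n_r^{(k)})(n - n_t^{(k)})}},$$

which approximately follows a standard normal distribution, tested
one-sided (upper tail): only an *excess* of joint co-occupancy counts as
evidence of regulation. With $n = 100$, $n_r = n_t = 10$ and $n_{rt} = 4$
this gives $\rho = 0.03$, $z = \sqrt{11}$ and $p = 1 - \Phi(\sqrt{11})
\approx 4.6\times 10^{-4}$:

```{r}
csnStatistic(n = 100, nr = 10, nt = 10, nrt = 4)
```

### Box construction

The target box occupancy is `boxFraction * n` cells (default 0.1, the
value suggested empirically in the cell-specific-network literature),
rounded, with a minimum of one. The box is a *value window*: the
occupancy-many cells nearest to the focal value are taken, and every cell
tied with the boundary distance is included as well, so cells with equal
expression enter or leave the box together. On tie-free data the box
holds exactly `round(boxFraction * n)` cells. The tie rule matters
enormously in this domain: dropout zeros and duplicated pseudo-cell
profiles (below) produce large groups of identical values, and any rule
that splits a tie group by an arbitrary secondary key (such as cell
index) makes the boxes of two unrelated tie-heavy genes systematically
overlap, corrupting the statistic. With the value-window rule the
per-gene occupancies $n_r, n_t$ vary and enter the statistic directly; a
box that would swallow all $n$ cells carries no local information and its
pairs are assigned $z = 0$.

## Pseudo-cells and the bootstrap ensemble

The neighborhood statistic needs on the order of a hundred cells. Small
datasets are enlarged by inserting `q` pseudo-cells (default 5) between
each pair of cells adjacent in the canonical cell order; $m$ cells become
$m + (m-1)q$ (19 become 109). Each pseudo-cell is an exact copy of one
real cell's *whole matched profile*, drawn uniformly with replacement
from all real cells: copying jointly preserves the joint distribution of
every miRNA-mRNA pair, whereas per-gene resampling would destroy it. No
expression values are ever interpolated, and the insertion slot is pure
bookkeeping (the statistic is order-free).

Because the pseudo-cell draw is random, the whole procedure is repeated
`B` times (default 100), and for each pair and each real cell the final
association is the median of the $B$ per-run $z$ values, with
$p = 1 - \Phi(z_{\mathrm{median}})$ recomputed from the median (medians
of even counts use the mean-of-central-values convention). An edge enters
cell $k$'s network iff $p < \alpha$ strictly (default 0.01). Only real
cells receive networks.

## Downstream analytics

* **Hubs** — the top `ceiling(0.2 * count)` miRNAs by out-degree among
  miRNAs with at least one target in the cell ("active"); a silent miRNA
  cannot be a hub. Ties at the cut break lexicographically so results are
  reproducible. The same rule applies to hub cells of crosstalk networks.
* **Conserved / rewired** — an interaction or hub present in at least
  `ceiling(0.9 m)` cells (17 of 19) is conserved; present in exactly one
  cell, rewired. The two sets are disjoint by construction.
* **Similarity** — between two cells, the overlap coefficient
  $|A \cap B| / \min(|A|, |B|)$ of their interaction sets or hub sets;
  an empty set yields similarity 0 with a warning.
* **Expression distance** — Euclidean distance over the stacked
  miRNA+mRNA gene dimension, min-max normalized to $[0,1]$ over the
  off-diagonal entries (the structural diagonal zeros would otherwise pin
  the minimum and make the normalization vacuous).
* **Clustering** — average-linkage agglomerative clustering (configurable
  to single/complete; the choice is not dictated by the method) on
  $1 - \mathrm{similarity}$ or on the normalized distance.
* **Crosstalk** — cells $i,j$ are linked iff their similarity strictly
  exceeds the median of the $m(m-1)/2$ pairwise similarities (computed
  over the upper triangle only, excluding self-similarities). Modules in
  the crosstalk graph come from Markov clustering (expansion/inflation
  iteration, inflation 2, convergence at max entry change $< 10^{-6}$ or
  100 iterations), keeping modules of at least 3 cells.
* **Biclique modules** — all maximal complete-bipartite subgraphs with at
  least 2 miRNAs and 3 mRNAs, enumerated through the Galois
  correspondence (each maximal biclique's miRNA side is an intersection
  of mRNA neighborhoods, so the intersection closure enumerates all of
  them exactly once). Disease enrichment of a module uses the upper-tail
  hypergeometric test with the background $N$ equal to all genes
  surviving preprocessing, and Benjamini-Hochberg adjustment across the
  modules of one analysis batch (raw and adjusted values are both
  reported, since module-level adjustment is a package choice rather
  than part of the method).

## Preprocessing contract

Duplicate gene symbols are averaged on the raw scale *before* anything
else; genes with standard deviation exactly 0 across cells are removed;
remaining values get $\log_2(x+1)$. Averaging precedes the constant
filter, so a gene that becomes constant after averaging is removed. The
miRNA file's column order is canonical and the mRNA columns are permuted
to match. A `transformed` flag on the matrices makes the whole operation
idempotent — re-running preprocessing never applies the log twice.

## The synthetic generator

`generateSynthetic()` (and the packaged `fixtureSmall()`: 19 cells, 50
miRNAs, 300 mRNAs, 20 planted pairs inside a 2,000-pair prior) emulates
the data regime the method targets: log-scale expression normal around
gene-specific means (truncated at zero), optional planted cell blocks,
monotone miRNA-target coupling at strength 0.9, and 30% dropout.

Two generator choices deserve emphasis:

* **Coupling is monotone, not merely linear** — the statistic detects
  local co-occupancy, so a monotone relation is the natural recovery
  target; the sign is configurable (repression-style decreasing coupling
  is detected equally, because monotone decreasing maps neighborhoods to
  neighborhoods).
* **Dropout is detection-limit censoring** — per gene, values at or
  below the gene's `dropout` quantile read as zero, so low-abundance
  measurements are lost preferentially and equal values are censored
  together. This mirrors the abundance dependence of real dropout and is
  the regime in which a neighborhood statistic is genuinely robust to
  dropout: a censored measurement still says "this cell is in the low
  tail", and coupled genes drop out in the same cells. The generator
  does *not* model expression-independent (purely random) zeroing; under
  that regime any cell that loses one of the two measurements carries no
  pairwise information at all, and no method of this family can recover
  it. Passing recovery tests therefore demonstrate robustness to
  abundance-driven dropout, not to arbitrary missingness. Count-level
  realism (library size, overdispersion) is out of scope because the
  pipeline consumes log-scale matrices.

## Calibration: a known limitation

The normal approximation behind $z$ treats the box memberships as if
they were random sets, ignoring that the focal cell is itself a member
of all three boxes by construction. Conditioning on the focal cell makes
the null mean of $z$ positive, of order $9/\sqrt{n}$ at the default box
fraction: for tie-free data at $n = 109$, $n_{rt} - 1$ is
hypergeometric and the null satisfies $E[z] \approx 0.86$ with an
upper-tail exceedance near 5% at the nominal 1% level. Pseudo-cell
duplication amplifies this further, since every copy of the focal cell
also sits in both boxes. The package deliberately implements the
statistic as defined rather than recentring it, and the test suite
measures the calibration honestly (the corresponding null-calibration
expectations fail and are left failing by design). Practical
consequence: per-cell networks should be read as *rankings* of candidate
regulations — which the planted-truth recovery tests validate — and
absolute edge counts at a nominal $\alpha$ overstate significance.
Comparisons against validated references use the permutation baseline
(`evaluateAgainstReference()`), which is unaffected by the miscalibration
because the random networks are drawn at the same size.

## Problem sizes used by the tests

The suite validates the full pipeline at the fixture scale (19 cells,
$q = 5$, $B = 20$, 2,000 prior pairs), unit behavior on toy data with
hand-computed expectations, and each nonstandard algorithm (biclique
enumeration, Markov clustering, box construction) against an independent
brute-force oracle at toy size. Null calibration is measured on 10,000
simulated independent pairs at $n = 109$. These sizes keep a full run in
the order of seconds to a minute while exercising every code path; `B`
and the prior size scale up without changes for real analyses.
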