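---
title: "Methods: single-cell biomarker discovery with scbiodisc"
author: "scbiodisc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell biomarker discovery with scbiodisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scbiodisc takes a genes × cells matrix of raw single-cell RNA-seq read
counts to a set of candidate biomarkers in four stages: preprocessing
(normalization and gene/cell filtering), cellular clustering with
robustness assessment and outlier detection, pseudo-temporal ordering, and
differential expression feeding decision-tree, network and enrichment
analyses. This vignette explains each model, its assumptions, the tunable
parameters, and the numerical choices made where the design was open. It
states no empirical result that the package's tests and acceptance script
do not themselves compute.

```{r}
library(scbiodisc)
ds  <- simulate_cells(synthetic_spec(seed = 1))
nr  <- compute_size_factors(ds$table)
tab <- filter_by_expression(nr, minexpr = 0, minnumber = 1)
cl  <- cluster_kmeans_gap(tab, k_range = 1:5)
```

## Normalization

Sequencing depth differs across cells, so raw counts are not comparable.
Two interpretations of depth normalization are implemented because the
common verbal description ("the ratio of the gene instantaneous median to
the total counts in that cell") is ambiguous:

* `scale_to_median_total` (default): cell $c$ gets size factor
  $s_c = T_c / \mathrm{median}_{c'} T_{c'}$ where $T_c$ is the cell's total
  biological count, so every normalized column sums to the median raw
  total. This matches the behaviour of the RaceID-style tools the pipeline
  descends from and is defined for any dataset.
* `median_of_ratios`: the DESeq-style estimator
  $s_c = \mathrm{median}_g \; x_{gc} / (\prod_{c'} x_{gc'})^{1/n}$ over
  genes expressed in every cell, rescaled to geometric mean 1. It is robust
  to composition effects but undefined when no gene is expressed in all
  cells — common in sparse single-cell data, which is why it is not the
  default.

Spike-in rows are excluded from factor estimation (their content is
technical, not biological) but divided by the same factors. Normalization
divides by a positive scalar per cell, so the zero pattern of the matrix is
preserved exactly. Normalized values are only ever shifted (+0.1 or +1)
inside logarithms for display; tests and statistics never see shifted
values.

## Gene and cell filtering

Three gene filters and one cell filter are available, all composable:

* **Expression filter**: keep genes with normalized expression ≥ `minexpr`
  in ≥ `minnumber` cells. The convenience mode `"median10pct"` sets
  `minexpr` to the overall median of normalized biological values and
  `minnumber` to 10% of the cells (rounded up) — the conventional
  case-study setting. The gene rule is evaluated on normalized values; the
  cell rule (`min_cell_counts`, typically 1000) on raw totals, because a
  cell's depth is a property of its library, not of its normalized profile.
  The filter is monotone: raising either threshold never adds genes.
* **Designed filter**: intersect with a user-supplied gene list, exact
  string match, preserving table order; absent list entries are reported.
* **Technical-noise filter**: see below.

Spike-ins are always removed from filtered output; every downstream stage
sees biological genes only.

## Spike-in technical-noise model

ERCC spike-ins are synthetic transcripts added at known concentration, so
their variability across cells is purely technical. Their squared
coefficient of variation is modelled as

$$\mathrm{CV}^2(\mu) = \frac{a_1}{\mu} + a_0,$$

the sum of Poisson sampling noise (the $a_1/\mu$ term, with $a_1 > 1$
absorbing efficiency losses) and a multiplicative noise floor $a_0$. The
curve is fitted to the spike-in (mean, CV²) pairs by a gamma-family GLM
with identity link on the regressor $1/\mu$ — a generalized least-squares
fit appropriate because the sampling error of a CV² estimate scales with
its magnitude. Spike-ins with mean below the 20th percentile are excluded
from the fit (`fit_quantile = 0.20`); their CV² estimates are dominated by
sampling error. At least 10 spike-ins with positive mean are required.

Each biological gene is then tested against the technical expectation
inflated by a minimum biological dispersion $\theta$ (`min_biol_disp`,
default 0.25, i.e. a biological CV of 0.5 that a gene must exceed to be
interesting):

$$\frac{(n-1)\,\hat v_g}{(a_1+\theta)\mu_g + (a_0+\theta)\mu_g^2}
  \;\sim\; \chi^2_{n-1} \quad \text{under the null,}$$

with genes kept when the upper-tail p-value is ≤ `alpha` (default 0.01).
**Known limitation**: the $\chi^2$ reference distribution is exact for
normally distributed expression; for strongly overdispersed low-mean
counts the sample variance is heavier-tailed than normal theory predicts
and the test is anti-conservative. The package's calibration test
therefore verifies type-I control in the near-Poisson moderate-mean regime
where the null model genuinely holds; on real low-coverage data the filter
should be read as a ranking device rather than a calibrated test.

## Clustering

All clustering operates on $\log_2(x+1)$ of normalized values — the log
stabilizes the NB mean–variance relation, and the +1 keeps zeros at zero.

**k-means with gap-statistic model selection.** For each $k$ in `k_range`,
k-means is run (best of `restarts = 10` seeded starts by within-cluster
dispersion $W_k$). Under the default `"pearson"` distance, assignment uses
the $1-r$ correlation dissimilarity with centroid recomputation in profile
space (profiles, not magnitudes, define cell identity); `"euclidean"` is
classical Lloyd. The "saturation level of the gap statistics" is
operationalized as the standard first-crossing rule: with $B$ =
`gap_refs = 50` reference datasets drawn uniformly over the per-gene data
range,

$$\mathrm{gap}(k) = \tfrac1B\sum_b \log W_k^{(b)} - \log W_k, \qquad
  s_k = \mathrm{sd}_b\bigl(\log W_k^{(b)}\bigr)\sqrt{1 + 1/B},$$

and the chosen $k$ is the smallest with
$\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - s_{k+1}$. This is the standard,
testable reading of gap-curve saturation. A user-fixed `k_fix` bypasses
selection; the curve is still computed and stored. Dissimilarity-space
k-means restarts draw seeded random initial centers, so labels are
reproducible for a fixed seed but k-means permutation equivariance holds
only up to the restart draw (the model-based path is equivariant).

**Model-based clustering.** Cells are reduced to
`n_pcs = min(20, n_cells − 1)` principal components of the log counts
(mixtures in the full gene space would be hopelessly singular) and a
Gaussian mixture is fitted by EM over diagonal and full covariance
families; the (k, family) pair with maximal BIC wins and cells take their
maximum-posterior assignment.

**Robustness.** Cluster stability is the per-cluster mean, over
`n_bootstrap = 50` bootstrap resamples of the cells, of the best Jaccard
similarity between the original cluster and any recluster of the resample
— both treated as sets of original cell indices restricted to the cells
present in the resample (an unsampled cell can count against no one). Ties
in the best-match search are broken by the lowest new-cluster index; a
cluster absent from every resample scores 0 with a warning. Values above
0.6 are conventionally read as stable. Consistency is the standard
silhouette width $s(i) = (b_i - a_i)/\max(a_i, b_i)$, with members of
singleton clusters assigned 0 by convention.

## Outlier cells

Within each cluster of ≥ 2 cells, the gene-level mean–variance relation is
fitted as a quadratic in log space,
$\log v = c_0 + c_1 \log m + c_2 (\log m)^2$, across genes with positive
mean and variance. Each raw count is scored by its negative-binomial
upper-tail probability under the cluster gene mean and the fitted
variance, with size $r = m^2/(v-m)$; when the fitted variance does not
exceed the mean the NB degenerates and a Poisson background is used (and
logged). A gene is an outlier gene in a cell when that probability falls
below `probthr` ($10^{-3}$ by default, the conventional setting of the
upstream tools, recorded in the report); a cell is an outlier when it has
at least `outminc` outlier genes — 2 by default, or `"5pct"` for 5% of the
filtered gene count (rounded up), the rule used on real case studies.
Scoring uses raw counts by default: outliers are aberrations of the
library, and normalization would partially absorb exactly the signal
sought — the flip side is that unusually deep cells can be flagged too.
Outliers are flagged, never re-assigned to new clusters; re-assignment is
a deliberate simplification left out of scope.

## Embeddings and heatmap ordering

PCA takes the top two components of the centered log counts (deterministic
up to sign; component variances non-increasing). tSNE uses the Barnes-Hut
implementation with a recorded seed and perplexity (default
$\min(30, \lfloor (n-1)/3 \rfloor - 1)$; values at or above $(n-1)/3$ are
rejected as the conditional perplexity would be undefined). For distance
heatmaps, clusters are arranged by single-linkage hierarchical clustering
of the cluster-center distance matrix, with center distance taken as the
mean cell-to-cell distance between the two clusters.

## Pseudo-temporal ordering

Trajectories are built over cluster centers, not individual cells: the
Euclidean minimum spanning tree of the centers in the clustering PC space
is taken, and its diameter (longest path by summed edge length, ties
broken by lexicographic cluster index) becomes the backbone — with no
prior knowledge of start and end states, the longest path through the tree
is the least arbitrary main axis. Every cell is projected orthogonally
onto its nearest backbone segment, clamped to the segment (a cell beyond a
terminal center gets the terminal arc length; extrapolation would let
noise stretch the axis), and pseudotime is the cumulative arc length to
the projection. Cells are ordered by pseudotime, ties by cell index.
Projection, rather than cluster-level rank, orders cells within clusters —
it uses strictly more information at no extra cost. The optional
rolling-mean smoother in `expression_along_order()` is display-only and
enters no statistic.

## Differential expression

**Resampled Wilcoxon test.** Wilcoxon rank statistics are depth-sensitive
when libraries differ in size, so every cell is first downsampled to the
minimum library depth by Poisson thinning (count $x$ becomes
$\mathrm{Poisson}(x \cdot d_{\min}/d_c)$; cells already at the minimum
keep their counts, making the procedure the identity at equal depths). Per
gene, the standardized rank-sum statistic

$$z_g = \frac{W_g - n_2(n+1)/2}{\sqrt{n_1 n_2 (n+1)/12}}$$

is computed on the thinned counts via the column-rank kernel
(`rank_columns`, mean ranks on ties) and averaged over
`n_resamples = 20` thinning draws. The variance formula is the no-ties
form even when thinned counts tie; the permutation null uses the same
form, so the calibration is internally consistent. The null distribution
comes from `n_permutations = 100` label permutations applied to the same
resampled rank matrices. q-values are SAM-style: at each observed
$|z|$ cut-point, $\widehat{\mathrm{FDR}} = (\mathrm{median\ permuted\ call
\ count} + 1) / \mathrm{observed\ call\ count}$, then each gene takes the
minimum over cut-points at or below its own statistic. The +1 is the
permutation-resolution correction: without it, the maximal observed
statistic exceeds every permutation in about half of all null datasets
(the observed labeling is exchangeable with the permutations) and would
receive $\widehat{\mathrm{FDR}} = 0$, a guaranteed false call; with it,
genuinely shifted genes still inherit the bulk cut-point FDR through the
monotonization, so power is unaffected. All-zero genes report statistic 0
and q = 1. Fold changes are $\log_2$ with pseudocount 0.5 on both group
means of depth-equalized counts, and the "fold change > 1" call threshold
is interpreted on the linear scale. The test runs on raw counts with
spike-ins excluded — normalized input would double-correct the depths.
Only the two-class unpaired design is provided.

**Binomial cluster markers.** For one cluster against the rest: with $T$
the target cluster's total count and $p_0$ the gene's share among the
remaining cells (pseudocount 0.5 on numerator and denominator), the
gene's target count $x$ is referred to $\mathrm{Binomial}(T, p_0)$ with
the two-sided convention $p = 2\min(P(X \ge x), P(X \le x), 0.5)$ —
fixed here because the upstream tools route this test through external
machinery whose exact tail convention is not documented. q-values are
Benjamini–Hochberg; fold change is $(x/T)/p_0$.

## Biomarker identification

**Decision trees.** The CART inducer is implemented directly: at each node
an exhaustive search over all features and all midpoint thresholds between
adjacent observed values finds the split minimizing weighted Gini
impurity; growth stops when a node is pure, smaller than
`minsplit = 20`, or when the impurity decrease relative to the root falls
below `cp = 0.01` (conventional recursive-partitioning defaults; the
exhaustive search is verified against both a brute-force enumeration and
an independent recursive-partitioning implementation in the tests). A
`"c45"` inducer maximizing gain ratio with the same stopping rules is
available but experimental — it has no error-based pruning. Trees export
to JSON and Graphviz DOT. Ten-fold stratified cross-validation (seeded
folds, sizes differing by at most one) pools held-out confusion counts;
sensitivity and specificity treat the named `positive` class (the target
cluster) as positive, and are reported alongside accuracy. Features constant
within a node are never chosen (no valid threshold exists).

**Network hubs.** DEG lists are intersected with an offline
protein–protein interaction edge list (weights in [0,1], e.g. STRING
combined scores / 1000). Edge weights act only as a confidence filter at
load time (`min_weight`); centrality treats the network as unweighted,
matching how hub analyses are conventionally reported. Degree and
betweenness (Brandes accumulation, each unordered pair once, unnormalized
by default with a normalization flag) rank hubs: descending degree, ties
by descending betweenness, then gene ID.

**Enrichment.** Gene sets (GMT) are tested by the one-sided
hypergeometric upper tail against a stated universe, BH-corrected across
sets. Query genes outside the universe are dropped with a warning; set
members are intersected with the universe before testing.

## Synthetic data generator

`synthetic_spec()` / `simulate_cells()` generate the statistical structure
the pipeline assumes, so every stage is testable offline:
negative-binomial counts (mean–size parameterization, variance
$\mu + \mu^2/r$, $r = 2$ by default — a typical single-cell
overdispersion) over log-normal baseline gene means, cluster structure
carried by disjoint marker sets at a fixed fold change (defaults: 3 equal
clusters of 300 cells total, 10 markers each at 8-fold), log-normal
library-size spread (sd 0.35, a typical depth spread), optional spike-ins
drawn so their variance follows $\mathrm{CV}^2 = a_1/\mu + a_0$ (defaults
$a_1 = 3$, $a_0 = 0.1$, in the range of published spike-in fits), an
optional linear trajectory (cluster means interpolated along a latent
position in $[0, k-1]$), and injected outlier cells whose chosen genes
have their NB *mean* multiplied before drawing — multiplying realized
counts would leave sampled zeros untouched and produce undetectable
"outliers".

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: zero inflation beyond the NB's own
zeros (no dropout model), batch effects, doublets, gene–gene correlation
within clusters, and ambient contamination. Recovery results on this
generator demonstrate correctness of the algorithms under their assumed
model, not robustness to real-data artifacts.

## Numerical choices and degenerate inputs

* Distances clamp small negative rounding residues to 0; diagonals are
  exactly 0. Constant cell profiles are an error under correlation
  distances (named in the message).
* Empty k-means clusters are re-seeded with the farthest point.
* NB tail probabilities collapse to Poisson when the fitted variance does
  not exceed the mean.
* q-values are floored at machine epsilon before $-\log_{10}$ display.
* All randomness flows from explicit seeds recorded in result objects and
  the pipeline manifest; `run_pipeline()` derives per-stage seeds from the
  single global seed by fixed offsets, and a rerun with identical
  configuration reproduces every result table byte for byte.

## Problem sizes used by the test suite

The statistical tests run at deliberately desk-scale sizes chosen as the
smallest that make the checks sharp: null and power simulations at
200 genes × 50–60 cells (20 null replicates; 50 replicates for the
FDR-control check at 100 × 30), noise-law recovery at 40 spike-ins ×
2000 cells, full recovery at the generator defaults (500 × 300), and
trajectory recovery at 150 × 60. `scripts/acceptance.R` recomputes the
same quantities from scratch at these sizes.

## Known limitations

* The technical-noise filter's chi-square null is anti-conservative for
  strongly overdispersed low-mean genes (see above).
* The Wilcoxon variance ignores ties introduced by thinning; with heavy
  ties the statistic is slightly conservative, identically in the observed
  and permuted statistics.
* Gap-statistic selection inherits k-means' sensitivity to non-spherical
  clusters; the model-based path is the alternative.
* The outlier model assumes within-cluster homogeneity; a misspecified k
  turns sub-structure into "outliers".
* Pseudotime is a single path through cluster centers: branching
  topologies are out of scope.
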