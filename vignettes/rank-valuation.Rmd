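---
title: "The rank-valuation (v) transform: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rank-valuation (v) transform: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmetric)
```

## The model

`vmetric` operates on strictly positive entity-by-sample abundance
matrices: proteomics quantification scores, microarray signal intensities,
or log2-scale induction factors converted to abundances via `x -> 2^x`
(`read_matrix(transform = "pow2")`). The working assumption is that each
sample's abundances approximately follow a Zipf / logarithmic
Boltzmann-type rank-abundance law

$$N_{(k)} \approx C \, k^{-\alpha},$$

with rank `k = 1` the largest value and `alpha` near 1 for "neutral" data.
Under that law, the valuation

$$v_{is} = \frac{\log\!\left(N_{is} / N_{\mathrm{top},s}\right)}{\log k_{is}},
  \qquad k_{is} \ge 2,$$

is exactly `-alpha` for every entity, independent of the per-sample scale
`C` and of the logarithm base (natural log is used internally; the base
cancels). On real data `v` oscillates around `-1`. The transform's virtue
for clustering is geometric: a large *multiplicative* excursion of one
entity moves it both in value and in rank, i.e. roughly *along* the
rank-abundance curve, leaving its `v` near `-alpha` — whereas the same
excursion stretches one coordinate of the raw Euclidean embedding by
orders of magnitude and can dominate every pairwise distance. Rank
assignment uses descending ordinal ranks with ties broken by input row
order, keeping each rank an integer `>= 2` usable as a logarithm base.

**Rank-1 exclusion.** At `k = 1` the expression is `0/0`, so entities
attaining rank 1 in *any* sample are removed from the output for *all*
samples (the union rule), and recorded in `excluded_rank1()`. The union is
computed once from the full ranking and is not re-identified per analysis
subset, so subsetting samples after the transform keeps the entity set
stable. With `S` samples at most `S` entities can be excluded; exactly one
is excluded when every sample shares the same top entity.

**Preconditions.** Ranking requires a complete, strictly positive matrix;
`filter_complete()` drops any entity with a missing, non-finite, zero or
negative value in any sample and reports each dropped id with its reason.
This mirrors the "observable in every sample" rule commonly applied when
per-run identification can fail, and it is applied *after* the `pow2`
transform (which is total, so the order cannot change the outcome).
Degenerate inputs fail loudly: an empty post-filter matrix, a one-entity
matrix (only rank 1 exists), zero-variance columns under the correlation
metric, both-zero-variance groups in the t test.

## Dissimilarities and the clustering harness

`pairwise()` computes sample-by-sample (or entity-by-entity)
dissimilarities: Euclidean, squared Euclidean ("E2"), half squared
Euclidean ("E2'"), correlation distance `1 - r`, and the RBF kernel
`exp(-gamma * ||x - z||^2)` — the latter a *similarity*, tagged as such and
refused by the agglomerator. The RBF bandwidth defaults to the median
heuristic `1 / median(||x - z||^2)` over distinct pairs and is recorded in
the output. `ann_index()` exposes the Clark–Evans aggregation ratio
`ANN = D_O / D_E` with `D_E = 0.5 / sqrt(n / A)` as a formula-level
primitive for planar point patterns.

`agglomerate()` implements the Lance–Williams recurrence with the
canonical coefficient table (see `?linkage_scheme`). Numerical and
interface choices:

* **Required inputs.** Centroid and median linkage are only meaningful on
  squared Euclidean input (merge heights are then squared distances
  between centroids / recursive midpoints); Ward requires half squared
  Euclidean (heights are then increases in total within-cluster sum of
  squares). The input matrix carries a `metric_name` tag and a mismatch is
  a contract error unless `waiver = TRUE`.
* **Heights** are reported in the units of the input dissimilarity — no
  square root is taken of E2/E2' heights. This differs from some packages'
  conventions; the test suite pins the exact dialect against
  `stats::hclust` fed the corresponding input.
* **Tie-breaks.** The globally closest pair is chosen by scanning active
  cluster slots in creation order and keeping the first strict minimum, so
  results are deterministic across platforms.
* **Monotonicity.** Single, complete, both averages and Ward cannot invert
  (non-decreasing heights); centroid and median can. `cut_tree(t, k)`
  therefore cuts by *merge order* (undoing the last `k - 1` merges), which
  is always well defined, rather than by height.

`kmeans_lloyd()` is plain Lloyd under squared Euclidean dissimilarity with
`restarts` (default 25) random initialisations, keeping the best
within-cluster sum of squares. It is deterministic given `seed`;
assignment ties go to the lowest cluster index; a cluster emptied during
iteration is re-seeded from the point farthest from its current centroid
(or left empty if all points coincide). A fixed, documented variant was
preferred over delegating to an external implementation so that seeded
runs are reproducible; `stats::kmeans(algorithm = "Lloyd")` serves as an
independent cross-check in the tests.

`agreement()` quantifies cross-method consistency with the pair-counting
(Rand) index, which is 1 exactly for partitions identical up to
relabelling. It reports the mean pairwise index (`overall`) and the
fraction of pairs agreeing exactly (`frac_identical`); given a reference
split it also reports which partitions separate the reference groups
exactly. Both views are reported because "the methods agree" and "the
methods are right" are different claims.

## Variance diagnostics, t tests, PCA

`variance_profile()` computes unbiased (`n - 1`) per-entity cross-sample
variances and their descending order. `flag_outliers()` aligns two
profiles rank-by-rank, counts the positions at which the scrutinised
profile exceeds the reference at the same rank, and flags that many
entities from the top of the scrutinised profile's own ordering (the
exceeding positions are kept for audit; on typical data the exceeding
positions are themselves the top ranks, making the two readings coincide).

`welch_test()` is the two-sided unequal-variance (Welch–Satterthwaite)
test via `stats::t.test`, with 95% per-group mean confidence intervals
from the t quantile. Welch was chosen because the two variance populations
being compared (raw vs v) differ in spread by orders of magnitude, where a
pooled-variance test is indefensible. In `run_study()` the "after
exclusion" comparison removes the flagged number of top-variance entities
from *each* profile's own ranking — the rule is symmetric because the
exclusion count, not the identity of the entities, is what the comparison
conditions on; the choice is recorded in the report. Raw variances are
computed over the same retained entity set as the v variances so the two
profiles align rank-by-rank.

`pca_report()` wraps `stats::prcomp` on the column-centered (optionally
scaled) matrix with entities as observations and samples as variables,
reporting the percentage of variance per component and the Pearson
correlation of each sample column with each component's scores. A
dimensionality-dominated dataset shows one component near 90% correlating
highly with every sample; a well-resolved one spreads components across
sample groups.

## The synthetic generator

`synth_spec()` / `generate()` produce matrices with exactly the structure
the transform presumes, plus the failure modes it is meant to survive:

$$N_{is} = C\, i^{-\alpha}\,
  \exp\!\big(\varepsilon_{is} + \delta\,[i \in P]\,[s\ \mathrm{treated}]
  + \eta_{is}\big),$$

with `eps ~ N(0, sigma^2)` replicate noise, a fixed perturbed entity subset
`P` (fraction `f`) shifted by `delta` in every non-control group (a shared
treatment signature), and sparse spikes `eta ~ N(0, tau^2)` occurring per
cell with probability `pi`. All draws are deterministic under `seed`; all
values are strictly positive by construction.

Defaults (chosen once, on these grounds):

| parameter | default | rationale |
|---|---|---|
| `n_entities` | 800 | the scale of a complete-case label-free LC/MS protein panel |
| groups | 3+2+2 control, 3+1 treated (11 samples) | a storage-study layout; `preset = "array6"` gives 3+3 |
| `zipf_exponent` | 1 | the neutral log-Boltzmann slope the transform assumes |
| `top_abundance` | 1e4 | typical top intensity scale; cancels in v |
| `replicate_noise_sd` | 0.15 | ~15% CV, a good label-free technical replicate |
| `effect_fraction` | 0.2 | a substantial but minority subset responds to treatment |
| `effect_size` | 2 | ~7.4-fold shift in the responsive subset |
| `spike_prob` | 0.02 | sparse contamination: ~16 corrupt cells per sample |
| `spike_sd` | 2 | heavy tail: ~7-fold typical, occasionally ≫ 50-fold |

What the generator emulates: per-sample power-law rank-abundance,
multiplicative replicate noise, a coherent group signature, and sparse
heavy-tailed corruption — the "sparse geometric distribution" of outlying
directions that makes raw high-dimensional Euclidean clustering
irreproducible. What it does **not** emulate: identification missingness
(completeness filtering is exercised with explicit masked fixtures
instead), correlated contamination (spikes are cell-independent),
entity-entity correlation structure, and instrument saturation. Passing
the synthetic experiment therefore shows robustness to *these* mechanisms
only, not to everything real LC/MS data can do.

## The consistency experiment and a known limitation

The headline experiment (`scripts/acceptance.R`, also asserted in the
acceptance tests) generates 50 seeded preset datasets, clusters samples
with all seven linkages on raw and on v values — each method on its
required dissimilarity — cuts every tree at `k = 2`, and scores each run
by whether all seven bipartitions are identical *and* equal the true
control/treated split. Problem sizes (800 entities, 11 samples, 50 seeds)
keep the full experiment in the tens of seconds while leaving the
per-sample rank structure realistic.

Raw clustering fails this bar in a majority of runs, as intended: single
spiked cells in high-abundance rows dominate Euclidean distances and
different linkages resolve the resulting outlier samples differently. The
v transform eliminates most of that — but not all, and the residual
failure mode is instructive. The transform normalises every sample by its
rank-1 value. When a heavy spike lifts some entity *above* the sample's
top entity, the hijacked normaliser shifts that sample's entire v vector
coherently by `log(F)/log(k)` per entity (`F` the factor by which the new
top exceeds the old), isolating the sample in v space; the rank-1 union
rule removes the offending *entity* but cannot repair the *normaliser*.
With the default spike regime this happens in an appreciable fraction of
seeds, so v-value clustering, while far more consistent than raw, does not
reach near-certainty; the acceptance report prints both measured rates.
Real datasets whose competing rank-1 entities are close in value — the
usual case when the top ranks are stable housekeeping species and only a
handful of entities ever attain rank 1 — sit in the benign regime. Users
with contamination-prone pipelines should inspect `excluded_rank1()` and
the per-sample top values before trusting a v-space dendrogram, and treat
a sample whose top value is an extreme outlier as suspect.

## Scope notes

* Delimited text (TSV/CSV) is the only input dialect; spreadsheet
  workbooks should be exported sheet-by-sheet to TSV first.
* The non-Archimedean formalism that motivates the transform is not
  implemented — only its computable consequence, the valuation above.
* Kernel PCA, kernel k-means, density clustering and nMDS embeddings are
  out of scope; the harness covers the seven Lance–Williams methods,
  Lloyd k-means, and the diagnostic surface described here.
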