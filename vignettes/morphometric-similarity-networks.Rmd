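---
title: "Morphometric similarity networks: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnkit)
```

## The model

A morphometric similarity network (MSN) describes one subject's cortex as a
weighted graph over the 68 Desikan-Killiany parcels. Region *i* is
represented by its vector of morphometric features; with the full feature
set these are seven T1w-derived metrics (cortical thickness CT [mm],
surface area SA [mm²], gray-matter volume GM [mm³], mean and Gaussian
curvature MC/GC [mm⁻¹, mm⁻²], folding and curvature indices FI/CI), the
T1w/T2w ratio (a myelin-sensitive contrast), and two diffusion metrics
(fractional anisotropy FA, mean diffusivity MD [mm²/s]). Raw features span
several orders of magnitude, so each feature is z-scored across the 68
regions (demeaned, divided by the sample SD) before the edge weight
`w[i, j]` is computed as the Pearson correlation of regions *i* and *j*'s
standardized feature vectors. Because every feature is zero-centered across
regions, the off-diagonal weights are approximately normally distributed
about zero; the diagonal is fixed at 0 and excluded from every statistic.

Three nested feature models mirror decreasing acquisition complexity:
`msn10` (all features), `msn8` (no diffusion), `msn7` (T1w only,
additionally dropping the T1w/T2w ratio). All model comparisons are
hierarchical against `msn10` as the reference — 10-vs-8 and 10-vs-7, never
8-vs-7 — which keeps the comparison count down and anchors everything to
the most information-rich network.

Networks are compared at matched edge densities. `threshold_density()`
retains the `k = round(d * n * (n - 1) / 2)` strongest off-diagonal edges,
so all networks compared at density *d* have identical edge counts, which
in turn makes nodal strength sums directly comparable without edge-count
normalization. The default density grid is 0.05–0.40 in steps of 0.05; the
endpoints are the sparsest and densest conditions reported individually.

## Similarity statistics

Four statistics quantify agreement between two node-aligned networks:

* `edge_correlation(mode = "all")` — Pearson over all off-diagonal weights;
* `edge_correlation(mode = "nonzero")` — Pearson restricted to elements
  suprathreshold in *both* networks. The union-zero exclusion (drop an
  element if either network zeroed it) is the stricter of the two readings
  of "zero present in the matrix for each model" and keeps the statistic
  symmetric in its arguments;
* `mantel_statistic()` — Pearson over the strictly lower triangles. On
  symmetric zero-diagonal matrices this is *algebraically identical* to the
  all-mode edge correlation (duplicating each (x, y) pair leaves Pearson r
  unchanged), a property the test suite asserts. It is kept as a separate
  statistic because the identity is not obvious, the half-matrix form is
  the one that admits a permutation test, and the equality breaks if a
  caller includes the diagonal;
* `replication_proportion()` — of the reference network's suprathreshold
  edges, the fraction also suprathreshold in the other network. At equal
  densities (equal edge counts) the statistic is symmetric.

Graph-strength differences between models are reported as paired-t effect
sizes `r = sqrt(t^2 / (t^2 + df))` rather than p-values: with a density
grid times contrasts times metrics, significance flags are uninformative
while effect sizes remain comparable.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analyses assume,
not biological detail. Per cohort it draws a shared regional loading matrix
(68 × `n_latent`, default 5) and per-feature latent weights; their product
is the group-mean standardized feature matrix. Each subject adds (a)
cell-wise Gaussian deviations (`subject_sd`, default 0.3) and (b) one
regional noise component *per MRI modality*, shared by all of that
modality's features (`modality_noise`, defaults T1w 0.4, T2w 0.6, DWI 0.6).
The modality-shared components are what make the nested-model question
non-trivial: dropping FA/MD removes the DWI component's subject-specific
information, so `msn8` genuinely differs from `msn10`, and `msn7` differs
more — the hierarchical ordering emerges from the generative structure
rather than being wired into any analysis. Finally each feature is affinely
rescaled into native units (GM ~10³, SA ~10², MD ~10⁻³, ...) so that the
z-scoring step has real work to do; defaults were set once to
order-of-magnitude realistic values.

Retest sessions mix the subject's session-1 random part with a fresh draw,
`noise2 = rho * noise1 + sqrt(1 - rho^2) * fresh`, which makes the
population test-retest correlation of every (region, feature) cell exactly
`rho` and reduces to identity at `rho = 1`. Cognition is
`beta * z(contrast' strength) + noise` for a fixed random contrast over the
full-density nodal-strength profile; `beta = 0` (the default, matching the
regime the cognition stage is expected to report) makes cognition
independent of every network measure. The three executive-function
subtests load 0.8 each on one latent factor, giving a compound-symmetric
correlation (pairwise r = 0.64) whose leading eigenvalue 1 + 2·0.64 ≈ 2.3
satisfies the PCA retention rule by construction.

What the generator does *not* emulate: spatial autocorrelation on the
cortical sheet, hemispheric symmetry, realistic cross-feature covariance
(the defaults are chosen for testability), site/scanner effects, or
outcome distributions with floor/ceiling effects. Passing tests therefore
demonstrate that the pipeline's statistics behave correctly under a
controlled generative model, not that real acquisitions will reproduce any
particular similarity level.

## Numerical choices

* **Sample SD in z-scoring** (n−1 denominator): the choice only rescales
  each standardized column by a common factor, so the MSN is invariant to
  it; the suite asserts scale-invariance to 1e−10 under affine feature
  rescaling.
* **Signed-weight ranking** in thresholding: the strongest similarities are
  retained, so large negative correlations are dropped first
  (`rank_by = "absolute"` is available for sensitivity analysis).
  Ties at the cutoff break by ascending (i, j) edge index and `k` rounds
  half away from zero; both rules are arbitrary but fixed, which buys exact
  reproducibility and makes retained edge sets nest monotonically in *d*.
* **Mantel permutation p** (off by default; the statistic is descriptive):
  two-sided with +1 smoothing, `p = (1 + #{|r*| >= |r|}) / (n_perm + 1)`;
  an exhaustive mode enumerates all node permutations for small matrices
  and is checked against a full-enumeration oracle.
* **Q² is pooled per CV instance**: one PRESS over all out-of-fold
  predictions, matching the single-sum form of the defining formula, rather
  than averaging per-fold Q² values.
* **Zero components is a first-class outcome**: c = 0 predicts the
  training-fold mean, so "no model" competes in the same Q² currency as
  every other component count. The retained count is the modal argmax over
  CV instances (ties break toward fewer components).
* **Stratified variant** uses equal-count outcome quartiles (rank-based,
  ties broken by order) and rebuilds each training set from equal-sized
  random per-bin samples — equal-count bins are the only construction that
  makes "equally sized samples from each bin" feasible for arbitrary
  outcome distributions.
* **PLS1 specifics**: NIPALS with standardized predictors (switchable);
  `c_max` defaults to 10, far below the rank limit of a 68-predictor
  matrix; a fit with `c_max` components yields predictions for every
  smaller count, so nested models cost one fit. The implementation is
  verified against an independent PLS implementation to 1e−10.
* **BCa bootstrap**: bias correction from the proportion of bootstrap
  weights below the point estimate (midrank treatment of ties, clamped
  away from 0/1), acceleration from jackknife skewness, and resampled
  weight vectors sign-aligned to the point estimate by dot product before
  interval construction (PLS component signs are arbitrary). With z0 = a =
  0 the interval provably reduces to the percentile interval. Note that
  for p ≈ n predictor matrices the bootstrap distribution of PLS weights
  is biased toward zero (resamples contain ~63% unique subjects), a regime
  where BCa corrects direction but not necessarily magnitude.
* **Seed discipline**: every stochastic operation takes an explicit seed;
  `run_pipeline()` expands its single seed into fixed per-stage offsets
  (+1000·stage) so stages are reproducible in isolation and full reruns
  are byte-identical.

## Open design decisions

* **Group networks average thresholded matrices** (the mean is then
  generally not itself at density *d*; it is re-thresholded only for binary
  comparisons). Averaging raw matrices before thresholding is implemented
  as `from = "raw"` since the choice is genuinely ambiguous.
* **Subjects are not excluded from the group mean** they are compared with;
  with realistic cohort sizes the own-subject contribution is negligible,
  and the simpler definition is easier to reason about.
* **Age is continuous** (uniform 22–36 years) in the generator even though
  the motivating cohort publishes age bins: the confound model needs a
  numeric covariate and the binning is a data-release artifact, not a
  method requirement. Categorical age enters naturally through the same
  design-matrix path if supplied.
* **Degree as a predictor** is implemented but nearly constant across
  subjects under exact equal-density thresholding (only tie patterns
  perturb it) — documented so its selection results are not over-read.

## Problem sizes

The test suite exercises the Monte-Carlo properties at sizes chosen to make
the qualitative results stable across seeds while keeping a full run fast:
20 seeded 50-subject cohorts for the model-hierarchy property, 3
reliabilities × 50 subjects for retest monotonicity, and 10 replicates of
200 subjects × 25 instances of 9-fold CV for the PLS null (with the
matching strong-coupling construction for signal recovery, where cognition
is a linear function of three nodes' strengths and recovery is measured as
recall of those nodes among the top-10 bootstrap weights).
`scripts/acceptance.R` recomputes the headline quantities at the same
sizes from a caller-supplied seed.

## Limitations

Everything upstream of the parcellated feature table — surface
reconstruction, registration, tensor fitting, myelin mapping, QC exclusion
— is out of scope; the package trusts its input tables. Only strength-family
nodal metrics are provided: MSN edges are statistical similarities, not
anatomical connections, so path-based graph metrics (efficiency,
clustering) rest on assumptions the phenotype does not support. The
synthetic generator's parameter defaults are calibrated for testability,
not biological realism, and results on synthetic cohorts quantify the
pipeline, not the brain.
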