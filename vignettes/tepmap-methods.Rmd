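---
title: "Methods: community detection for dense TMS-EEG response maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community detection for dense TMS-EEG response maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepmap)
```

## The analysis model

A dense TMS-EEG mapping experiment yields, per stimulation condition
(site × coil orientation), a trial-averaged TMS-evoked potential (TEP):
a channels × timepoints voltage matrix. `tepmap` analyses the 20–500 ms
post-stimulus window — at 1 kHz sampling and with both endpoints included
this is exactly 481 samples — because earlier samples are dominated by
the pulse artifact and later ones by baseline drift.

The pipeline's central object is built in three correlation steps:

1. **TEP connectivity.** For one condition, the channel time series are
   Pearson-correlated with each other, giving a channels × channels
   matrix (95 × 95 on the reference montage).
2. **Feature rows.** Each connectivity matrix is flattened *in full*
   (diagonal and both triangles retained) into one row. The full
   flattening is deliberate: the feature dimension is then exactly
   `n_channels²` (9025 = 95²), and the perfectly redundant entries cancel
   in the subsequent correlation, so nothing is gained by dropping them
   and the bookkeeping stays transparent. The same construction
   transposed — per channel, conditions correlated across time, the
   conditions × conditions matrix flattened — gives the recording-channel
   perspective with `n_conditions²` features.
3. **Similarity graph.** Feature rows are Pearson-correlated pairwise
   into the square symmetric matrix `A` whose entries, including the
   negative ones, are the signed edge weights for community detection.

Before feature construction the subjective-distress covariate (SUDS,
0–100) is regressed out of every (channel, timepoint) cell across
conditions by ordinary least squares *with an intercept*; whether to
include an intercept was an open choice and we include it because the
residuals should be interpretable as deviations from the covariate-free
mean response. The same residualization is applied, separately, to the
ROI-level measures before group tests.

## Signed modularity and its conventions

Partitions are scored by modularity with resolution $\gamma$:

$$Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \gamma\frac{k_i k_j}{2m}\right)
\delta(c_i, c_j)$$

extended to signed graphs asymmetrically,
$Q^* = Q^+ - \frac{m^-}{m^+ + m^-}\,Q^-$, where $Q^\pm$ is the plain
modularity of the positive/negative subnetwork with its own null model.
The asymmetry encodes that placing positively correlated nodes together
is the primary goal while negative within-community weight acts only as a
(bounded) penalty.

Two conventions deserve explicit statement:

* **Diagonal.** Self-weights are zeroed and the null-model term keeps
  the $i=j$ pairs. Under this convention two equal disconnected cliques
  score exactly $Q = 1/2$, the behaviour of the standard signed-Louvain
  toolboxes. The variant that drops $i=j$ from the null sum (the literal
  reading of the displayed formula) is available via
  `null_self_pairs = FALSE`; it scores the same two cliques at $2/3$.
* **Thresholding.** The similarity matrix is passed to the optimizer in
  full, negative correlations included — the asymmetric treatment exists
  precisely so that no threshold is needed.

`louvain_signed()` performs greedy local moves (random node visit order,
controlled by `seed`) followed by community aggregation, repeated until
no single-node move improves $Q^*$; a move must improve $Q^*$ by more
than $10^{-12}$ to be accepted, which makes the algorithm insensitive to
floating-point ties. The returned partition is additionally guarded never
to score below the all-singletons or one-community baselines. Labels are
canonicalized by decreasing community size, ties broken by smallest
member index.

## Consensus

The number of communities is emergent, never fixed in advance. Because
single Louvain runs are stochastic, the reported partition is a
consensus: `n_runs` runs (default 1000; run $r$ uses `seed + r`) are
summarized by their co-assignment matrix, entries below the co-assignment
rate expected under independently permuted run labels are zeroed, and the
thresholded agreement graph is re-clustered with the same number of runs,
iterating until every run agrees (at most 20 iterations, then an error —
silent non-convergence would hide genuine ambiguity). The mean and spread
of per-run $Q^*$ are reported alongside. The consensus construction was
an open design point; the agreement-matrix procedure was chosen because
it is deterministic given seeds and degrades gracefully: on unambiguous
structure every run already agrees and the first iteration exits.

Validation conditions are mapped onto discovery communities either by the
Euclidean nearest discovery neighbour or by majority vote among the 5
most correlated discovery rows, frequency ties going to the tied
community with the higher mean correlation. The top-5 rule is a genuine
majority rule: a validation row identical to a discovery row inherits
that row's label only when its community also wins the vote in that
neighbourhood.

## Coil-orientation sensitivity

Per **site**, COS is categorical — the two orientations land in the same
community (low) or not (high) — plus the continuous dissimilarity
$1 - r$ between the paired feature rows. Under random assignment into
$k$ equal communities the chance of a match is $1/k$ (1/2 for two, 1/3
for three); the package's agreement machinery reproduces these rates in
simulation, which is the calibration the categorical measure rests on.

Per **channel**, COS is the signed modularity of that channel's
conditions × conditions similarity matrix evaluated at the *fixed*
two-group orthogonal/parallel labeling (left + N45 and right + P45 are
orthogonal to the central sulcus; the complementary combinations are
parallel; midline sites follow a configurable rule, by default the
left-hemisphere one, and the rule is recorded on the labeling object).
No optimization is involved. Significance comes from shuffling the group
labels (preserving group sizes, since the observed labeling fixes them)
`n_perm` times and the add-one estimator
$p = (1 + \#\{Q_{null} \ge Q_{obs}\})/(1 + n_{perm})$, which can never
return 0 and is slightly conservative — the correct direction for a
marginal per-channel scan that applies no spatial correction.

## ROI measures and group statistics

Stimulation ROIs are the vertices whose simulated E-field *strictly*
exceeds 70 V/m (strictness is documented and configurable; values exactly
at threshold do not activate). Scalar maps (myelin, thickness) are
averaged over ROI vertices; tract counts are normalized by the geometric
mean of the connected areas, $c_{ij}/\sqrt{a_i b_j}$; degree is the sum
of a connectivity measure from the ROI across all 100 parcels, and each
of the 7 networks receives its fraction of that total (fractions sum to
1 whenever the total is positive; a zero total returns missing fractions
with a warning rather than a silent 0/0).

Measures are compared across response communities nonparametrically:
Kruskal–Wallis omnibus (rank-based H with tie correction, $\chi^2_{k-1}$
reference; the all-identical degenerate case is defined as $H=0, p=1$),
and — only when the omnibus is significant at $\alpha$ — pairwise
comparisons. "Rank-sum with Tukey correction" is internally ambiguous as
a recipe, so the package implements the realization common in standard
statistical software: pairwise mean-rank differences referred to the
studentized-range distribution for the $k$-group family (Tukey–Kramer),
with plain pairwise Wilcoxon rank-sum plus Holm exposed as
`method = "ranksum_holm"`. Whether the covariate should be residualized
out of each measure or modelled inside the test was ambiguous too;
residualization was chosen because it keeps the test fully nonparametric.

## The synthetic generator

`simulate_tep_dataset()` emulates the statistical structure the analysis
assumes, not the biophysics:

* Channels and sites sit on a deterministic Fibonacci-spiral layout over
  the upper hemisphere of a 90 mm sphere.
* Each planted community owns a spatiotemporal template: three
  damped-oscillation components (early/mid/late bands near 35, 100 and
  190 ms, latency bands offset per community so communities never share
  a peak time; frequencies ~30/11/5 Hz; decays 18/45/90 ms; amplitudes
  6/4/3 µV) with dipole-like difference-of-Gaussians topographies at
  randomly drawn scalp positions per community.
* The P45 condition of a site is the N45 template with the dipole
  geometry rotated 90° about the vertex axis, mixed in by the per-site
  `orientation_sensitivity` scalar in [0, 1] (default 0.2 — a mild,
  sub-community-level effect, so paired orientations co-cluster by
  default and high-COS sites must be planted deliberately).
* Noise is i.i.d. Gaussian per channel-timepoint with
  SD = template RMS / `snr` (default snr 5); SUDS is uniform on
  [0, 100] with optional linear leakage into TEP amplitude
  (`suds_leakage`, default 0).

E-field maps plant one contiguous supra-threshold vertex block per
condition (all values strictly between 70 V/m and `peak_field`, the rest
below 55 V/m), so downstream thresholding recovers the planted ROI
exactly. Connectome stacks draw tract counts from a Poisson (base rate 5)
and the fMRI/EEG connectivity modalities from folded normals
(mean 0.5, SD 0.3), with additive per-community mean shifts available to
plant group effects; parcels carry 7 contiguous network blocks.

What the generator does **not** emulate: realistic lead fields or volume
conduction, trial-level variability (only trial averages), spatially
correlated noise, artifact topographies, or any coupling between the TEP
communities and the connectome modalities beyond the explicitly planted
mean shifts. Passing tests therefore demonstrate that the pipeline
recovers the structure it is designed to detect under its own
assumptions — not that recorded data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Pearson correlations use the standard $1/(n-1)$ normalization with
  mean-centering before products; symmetry and unit diagonals are exact
  to $10^{-12}$ and enforced.
* Zero-variance channels, constant feature rows and constant covariates
  are flagged errors (or, for the covariate, a warning with
  mean-centering) naming the offending entity — never silent NaNs.
* Similarity matrices asymmetric beyond $10^{-10}$ are rejected.
* An edgeless graph has modularity defined as 0 with a warning.
* Degenerate permutation nulls (constant similarity) warn and return
  $p = 1$.

## Problem sizes used in the bundled checks

The test-suite and acceptance-script simulations are sized to give stable
statistical answers while staying small: planted-recovery checks use 30
sites (60 conditions, 20 per community) at the full 95 × 481 resolution
with 200 consensus runs; null-calibration checks use 21 sites across
20 seeds at 500 permutations per channel; chance-match rates use 10⁵
simulated pairs; the Kruskal–Wallis type-I rate uses 1000 null
simulations of 3 × 40 values. At these sizes all calibration bands
(match rates within ±0.005, significance rates within ±0.02 of nominal)
are comfortably resolved.

## Known limitations

* The Louvain optimizer is exact only in the limit of many restarts; on
  small graphs the bundled tests verify it attains the exhaustive
  optimum, but single runs on near-degenerate structure can land in
  local optima — hence the consensus layer.
* Channel-COS p-values are marginal per channel; no spatial/multiplicity
  correction across channels is applied or claimed.
* ROI machinery operates on one abstract vertex indexing per modality;
  cross-space resampling (surface/volume registration) must happen
  upstream.
* The pipeline consumes trial-averaged TEPs; preprocessing quality
  (artifact removal, trial rejection) is entirely upstream of this
  package.
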