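---
title: "Tractometry with tractometr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tractometry with tractometr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractometr)
```

## The problem

Diffusion-MRI tractography produces a *tractogram*: thousands to millions of
streamlines, each an ordered polyline through the brain's white matter in
world millimetres. Tractometry turns this into interpretable measurements in
three steps: (1) recognize which streamlines belong to known anatomical
tracts, (2) clean each recognized bundle of spurious members, and
(3) collapse the tissue properties along each tract into a fixed-length
1-D *tract profile* that can be compared across subjects. `tractometr`
implements these steps plus the downstream statistics that tract profiles
feed: point-wise group models with FDR control, exponential learning-curve
fits for sample-size planning, and 1-D augmentation operators for machine
learning pipelines. A synthetic phantom generator produces every input with
known ground truth, so the whole pipeline is exercised without imaging data.

## Coordinate conventions

All geometry lives in world mm, RAS (+x right, +y anterior, +z superior).
Volumes carry a 4x4 affine mapping 0-based voxel indices to the world
coordinates of voxel centers (the NIfTI convention). The inter-hemispheric
midline is the plane x = 0; a streamline *crosses* it only on a strict sign
change of x — touching the plane does not count, which makes the boundary
behavior deterministic. A point is *inside* a binary ROI iff its nearest
integer voxel index (round half away from zero per axis, after the inverse
affine) is a mask voxel; distances to an ROI are Euclidean distances to the
nearest mask-voxel center. TRK files are converted from their corner-origin
voxel-scaled coordinates using the header affine; TCK files are already in
world mm. Files whose headers carry no usable affine are rejected rather
than guessed at.

## Bundle recognition

Each tract is described by a `bundle_criteria()` record; every criterion is
optional. Configured criteria are applied to every candidate streamline in a
fixed order:

1. `prob_map` — mean probability sampled along the 100-node resampled
   streamline must be *strictly* greater than the threshold (default 0).
   The statistic is the mean, not the minimum: a single low-probability
   node (e.g. a voxel grazing the map edge) should not veto an otherwise
   well-supported streamline. This choice, and the default threshold, are
   package decisions; only "above a certain threshold" is prescribed by
   the method family.
2. `cross_midline` — tri-state: `TRUE` requires a strict crossing, `FALSE`
   forbids one, `NULL` leaves the streamline unconstrained.
3. `start` / 4. `end` — nearest-voxel membership of the first/last point,
   with no tolerance (tolerances are granted only to inclusion/exclusion
   ROIs). A streamline satisfying the pair only after reversal is flipped
   and accepted, so recognized bundles come out oriented start-to-end.
   When both are configured the pair is tested jointly (a flip must fix
   both ends at once) and rejections are tallied under `start`.
5. `length` — total polyline arc length within `[min_len, max_len]`,
   inclusive.
6. `primary_axis` — at least the given percentage of the streamline's
   movement must lie along the named axis. Movement is summed per segment
   (`sum |dx|` etc.), not endpoint-to-endpoint: a streamline that wanders
   up and down the z axis *travels* mostly in z even if its endpoints are
   level, and the per-segment reading matches that intuition.
7. `include` — the streamline must come within `tol` mm of **every**
   waypoint ROI.
8. `exclude` — it must stay farther than `tol` mm from **all** exclusion
   ROIs.
9. `shape_prior` — minimum MDF distance (20 comparison points) to a
   reference streamline must not exceed the centroid threshold. This is a
   deliberately reduced form of model-based recognition: no registration,
   no cluster pruning, just the distance test.
10. `qb_thresh` / 11. `mahal` — set-level cleaning of the survivors (next
    section).

Because the criteria act as a filter cascade, a streamline is tallied under
the *first* criterion that rejects it; removing any criterion can only grow
the accepted set. A streamline that survives the cascade for several tracts
is assigned to the first tract in the definition set, and a warning naming
the streamline and both tracts is recorded (collected on the result object,
not printed mid-run).

## Cleaning

`mahalanobis_clean()` removes streamlines that are unusually long or far
from the rest of the bundle. All streamlines are resampled to
`n_points` (default 100) nodes and flip-aligned to the first streamline so
that node indices correspond. Per round, a streamline is removed if its
mean-over-nodes Mahalanobis distance from the node-wise mean (under the
node-wise 3x3 covariance) exceeds `distance_threshold` (default 3) or its
length z-score exceeds `length_threshold` (default 4). Iteration stops at
a fixed point, after `clean_rounds` (default 5), or when a removal would
drop the bundle below `min_sl` (default 20) — that removal is skipped, with
a logged note. The defaults follow the established cleaning settings of
the reference tractometry literature and are all overridable. Aggregating
node distances by the *mean* (rather than the max) is a package decision;
the max would make the test much more sensitive to a single displaced node.

Node covariances are regularized with a ridge of
`1e-6 x (bundle spread)^2` (plus a tiny absolute floor) before inversion,
where the spread is the mean over nodes of the total node variance. This
keeps exactly collinear phantoms — zero transverse variance — from
producing singular covariances. Covariances use the population (1/n)
normalization so that node statistics, and therefore profile weights, are
exactly invariant under duplicating every streamline.

`qb_threshold_clean()` is a greedy single-pass clustering under the MDF
distance at 12 comparison points: each streamline joins the first cluster
whose running centroid is within the threshold (centroids are running
means, flip-aligned), else opens a new cluster. The **largest** cluster is
retained, ties going to the earliest-created one. The retention rule is not
prescribed anywhere citable; keeping the largest cluster is the
conservative reading of "cleaning" (drop stragglers, keep the core).
Cluster *assignment* can depend on scan order, which is why the tests
require only that the largest-cluster membership is stable under
permutation on well-separated bundles.

## Profiles

`resample_streamline()` places `n` points (default 100, the field's usual
node count) at uniform arc-length positions on the polyline, by linear
interpolation — no spline smoothing, so the operation is exactly checkable
against a segment-walking oracle. Scalars are sampled trilinearly at the
resampled node coordinates (i.e., after the final resampling, not at the
original vertices). Out-of-grid samples return 0 and are counted rather
than raising: streamline endpoints routinely graze the field of view and a
hard failure there would be brittle.

The profile value at node n is a weighted mean over streamlines with
Gaussian trajectory weights: `w = exp(-d^2/2)` where d is the node-wise
Mahalanobis distance from the node-wise **mean** position, normalized per
node. Streamlines that stray from the bundle core therefore contribute
less. The reference description speaks of similarity to the *median*
position; this package follows the established implementation in using the
node-wise mean (with ridge-regularized covariance) for the weights, and
reserves the node-wise median reference for `orient_bundle(mode =
"median")`, which flips each streamline iff that reduces its distance to
the median reference. Single-streamline bundles bypass weighting entirely
(weight 1; no covariance is estimable).

## Point-wise statistics

`pointwise_group_model()` fits, at every node, an ordinary least-squares
regression of the metric on a two-level group indicator plus covariates
(e.g. age, sex), and reports the two-sided t-test on the group coefficient.
The group-coefficient test (rather than an omnibus F) is the package's
choice; it matches the common use of the model as a group comparison
adjusted for covariates. All nodes share one design matrix, so the fit is
a single QR decomposition applied to the subjects x nodes response matrix.
Constant responses at a node yield p = 1 with a warning. `bh_fdr()` applies
the Benjamini–Hochberg step-up over the supplied family — by convention the
100 nodes of one (tract, metric) pair; pool several pairs into one call to
widen the family. `median_impute()` fills missing feature values with the
per-feature median of *its own* set, train and test separately, so no
training information leaks into evaluation.

## Learning curves

`learning_curve()` implements
`R2(x) = alpha - (alpha - beta) * exp(-(x - x_min)/kappa)`: performance
rises from `beta` at the smallest training size toward the asymptote
`alpha`; at `x = x_min + kappa` the curve has closed `1 - exp(-1)` (about
63%) of the gap, which is the operational meaning of `kappa`.
`fit_learning_curve()` pins `alpha` to the highest observed score and fits
`beta` and `kappa` by multi-start Levenberg–Marquardt least squares
(`kappa` starts at `x_min`, `2 x_min` and `max(sizes)`; bounded positive).

A caveat worth knowing: pinning `alpha` to the best *observed* score biases
the fit whenever the observed sizes stop short of the plateau, because the
unclosed remainder of the gap is folded into `beta` and `kappa`. On the
canonical size grid (100–1453) with a generating `kappa` of ~400, the
constrained least-squares optimum sits roughly 10% below the generating
`kappa` even for noiseless data — this is a property of the protocol, not
of the optimizer, which the tests verify reaches the constrained global
optimum. Supplying a known asymptote via the optional `alpha` argument
removes the bias.

## Augmentation

`augment()` operates on samples x nodes x channels profile tensors, each
operator controlled by one magnitude `m` scaled to the per-channel value
range: **jitter** adds i.i.d. noise with SD `m x range`; **scaling**
multiplies each sample's deviations from the channel mean by a factor from
Normal(1, m) truncated at 0 (the distribution family is a package choice;
only the single-magnitude parametrization is prescribed); **timewarp**
displaces 4 interior knots of the node axis by Normal(0, m), keeps the warp
monotone with fixed endpoints, and re-interpolates — one warp per sample,
shared across that sample's channels. `m = 0` is the exact identity for all
three, and every operator takes an explicit seed and leaves the caller's
RNG state untouched.

## The phantom generator

`make_phantom()` builds everything the pipeline consumes on a 60^3 grid of
2 mm voxels: bundles of 100-point streamlines sampled around parametric
curves (per-streamline transverse offset ~ Normal(0, spread^2) in the
curve's normal plane, plus per-point isotropic noise; about half of the
streamlines are emitted reversed so that orientation handling is always
exercised), distractors as smoothed random walks, spherical waypoint ROIs
at curve parameters 0.25/0.75 and endpoint ROIs at 0/1, scalar volumes
painted with the planted profile p(t) by nearest-curve-parameter assignment
within a tube of radius 2 x spread (background 0.1 elsewhere), and a
smoothed-occupancy probability map. The default study conditions — two
78 mm arcs of 60 streamlines each (spread 1.5 mm, noise 0.2 mm) plus 100
distractors — keep recognition exactly solvable (the arcs are separated by
far more than 3x their spread) while remaining seconds-scale.

What the phantom does *not* emulate: crossing/kissing fiber geometry,
registration error, partial-volume anatomy, or any diffusion signal model.
Passing tests on the phantom therefore demonstrate the correctness of the
geometry, recognition logic, weighting and statistics — not recognition
robustness on real, messy tractograms. One visible consequence of the
simplified painting model is a small negative bias in recovered profiles
where the planted value is far from background, from tube-edge
partial-volume blending; it stays within the 5%-of-range recovery bound at
the default conditions.

Group datasets (`make_group_dataset()`) use a smooth random Fourier base
profile per subject plus node-wise noise, with the group-2 shift planted at
chosen nodes as a multiple of the noise SD; learning-curve data
(`make_learning_data()`) inverts the curve model directly on the canonical
size grid 100, 175, 350, 700, 1000, 1453. Every generator is a pure
function of its explicit seed.

## Problem sizes used by the test suite

The suite runs the standard phantom (220 streamlines), 200 null
simulations of 100-node group datasets (n = 40 subjects each) for the
type-I calibration, 50 random bundles for the cleaning guard-rail
property, 20 noisy learning-curve replicates and 10^5 Monte-Carlo draws
for the jitter contract. These sizes make the whole suite run in well
under a minute while leaving the statistical checks adequately powered.

## Worked example

```{r example, eval = FALSE}
ph <- make_phantom(default_phantom_bundles(), n_distractors = 100, seed = 1)
defs <- phantom_definitions(ph)
res <- recognize(ph$tractogram, defs)
res
#> recognition result: 120/220 streamlines assigned, 0 warning(s)
#>   arc_low: 60 streamlines
#>   arc_high: 60 streamlines

pr <- extract_profile(res$bundles$arc_low$streamlines, ph$scalars$FA,
                      n_nodes = 100, tract_name = "arc_low")
pr
#> tract profile: arc_low / FA, 100 nodes, mean 0.4267
```

## Known limitations

- ROIs and scalar volumes must already live on the subject grid; no
  resampling or registration is performed, and volumes on a different grid
  are rejected.
- TRK support covers header-version-2 files with a valid `vox_to_ras`
  affine; older affine-less TRK headers are rejected explicitly.
- The shape-prior criterion is a distance test against reference
  streamlines, not a full model-based recognition with registration.
- The per-node model is ordinary least squares; mixed-effects and
  smooth-curve (GAM) alternatives are out of scope.
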