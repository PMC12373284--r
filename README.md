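# tractometr

Tractometry in R: recognize white-matter bundles in a tractogram, clean
them, extract along-tract tissue-property profiles, and analyze those
profiles statistically — all testable end to end on synthetic streamline
phantoms with known ground truth.

## Who this is for

Researchers working with diffusion-MRI derivatives — a tractogram
(TRK/TCK), scalar maps such as FA/MD/MK (NIfTI), and ROI masks in subject
space — who want per-tract, per-node measurements and the standard
statistics on top of them, without a Python stack. It is equally usable as
a pure simulation/statistics toolkit: every input can be generated
synthetically.

## What it computes

**Recognition.** Each tract is defined by optional criteria applied to
every streamline in a fixed cascade: probability map, midline crossing,
start/end ROIs, length range, primary travel axis, inclusion (waypoint)
ROIs, exclusion ROIs, a shape prior (minimum MDF distance to reference
streamlines), then set-level QuickBundles-threshold and Mahalanobis
cleaning. MDF is the minimum direct-flip distance
`min(mean_i |a_i - b_i|, mean_i |a_i - b_(n-1-i)|)` on equally resampled
streamlines. A streamline passing the cascade for several tracts goes to
the first tract in the definition set, with a recorded warning.

**Cleaning.** Iterative removal of streamlines whose length z-score
exceeds 4 or whose mean node-wise Mahalanobis distance from the bundle
core exceeds 3, for at most 5 rounds, never dropping below 20 streamlines
(all configurable); plus greedy MDF clustering that keeps the largest
cluster under a millimetre threshold.

**Profiles.** Each streamline is resampled to 100 equidistant nodes; the
scalar volume is sampled trilinearly at each node point, and the profile is
the node-wise weighted mean with Gaussian trajectory weights
`w_sn ∝ exp(-d_sn^2 / 2)`, where `d_sn` is the Mahalanobis distance of
streamline s's node-n point from the node-wise bundle center.

**Statistics.** Per-node OLS of the metric on group + covariates with a
two-sided t-test on the group coefficient and Benjamini–Hochberg FDR over
the nodes of a tract; median imputation applied within train/test sets
separately; the exponential learning curve
`R²(x) = α − (α − β) e^{−(x − x_min)/κ}` (α pinned to the best observed
score, β and κ fitted by multi-start Levenberg–Marquardt) — κ is the number
of additional subjects at which ~63% (`1 − e^{−1}`) of the α−β gap is
closed; and jitter / scaling / time-warp augmentation of profile tensors,
each driven by a single magnitude scaled to the per-channel range.

## Worked example

```r
library(tractometr)

# a synthetic subject: two arc bundles + 100 distractor streamlines,
# an FA volume with planted profiles, waypoint/endpoint ROIs
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
#> tract profile: arc_low / FA, 100 nodes, mean 0.4223
round(pr$values[c(1, 25, 50, 75, 100)], 3)
#> [1] 0.298 0.433 0.497 0.438 0.297
```

All 120 planted bundle streamlines are recovered (none of the 100
distractors is), and the extracted profile tracks the planted
`0.3 + 0.2 sin(pi t)` curve: ~0.30 at the tract ends, ~0.50 at mid-tract.

```r
dat <- make_learning_data(alpha = 0.62, beta = 0.38, kappa = 413)
fit_learning_curve(dat$size, dat$score)
#> learning curve: alpha = 0.6109 (fixed), beta = 0.3783, kappa = 373.6, x_min = 100, RSS = 5.82e-05
```

(The κ estimate sits below the generating 413 because α is pinned to the
best *observed* score; see the methods vignette for why, and for the
`alpha` override that removes the bias.)

A command-line wrapper over the same functions ships at
`inst/cli/tractometr` with subcommands `recognize`, `profile`, `clean`,
`stats` and `simulate`; configurations are YAML or JSON.

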