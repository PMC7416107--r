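---
title: "Decoding natural sounds from visual cortex: models and methods"
author: "soundmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding natural sounds from visual cortex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Complex natural sounds evoke spatial patterns of BOLD activity in early
"visual" cortex (V1–V3) that a classifier can distinguish, even in people who
have never seen — evidence that auditory feedback reaches retinotopic cortex
independently of visual imagery. The analysis that establishes this is a
multi-stage pipeline: block-design fMRI runs are reduced to single-block GLM
beta patterns, the three sound categories are decoded with cross-validated
linear SVMs inside retinotopically defined regions of interest, accuracies
are tested non-parametrically at the subject and group level, eccentricity
gradients are examined with repeated-measures ANOVAs and rank tests, and a
cubic searchlight maps decodable information across the whole volume.

`soundmvpa` implements that pipeline end to end, together with a synthetic
cohort generator so that every stage can be exercised, calibrated and tested
without access to scanner data.

## The synthetic cohort generator

The generator emulates the blocked auditory design: three natural-sound
conditions (forest, crowd, traffic), 6 repetitions each per run in a
pseudo-random order with no immediate repeats, 12 s blocks alternating with
12 s of silence, TR 2 s, four runs per subject. With a 6-volume lead-in this
yields 222 volumes per run; the short variant (6 s / 6 s, 9-volume lead-in)
yields 117. The lead-in/lead-out split is a convention exposed in
`build_schedule()`: the printed totals constrain only the sum.

Per voxel the simulated signal is

* baseline 100, plus
* a condition-common response (percent signal change, `amplitude`) for the
  sound-versus-rest boxcar, convolved with a canonical double-gamma HRF
  (gamma shapes 6 and 16, rate 1; peak ≈ 5 s, undershoot ≈ 15 s, ratio 6),
* a condition-specific pattern increment, drawn once per subject per voxel,
  fixed across runs, scaled by the voxel's region discriminability `d` (in
  units of the noise SD) and centred across conditions — so univariate
  sound-versus-rest responses are condition-equal by construction and all
  decodable signal lives in the multivoxel pattern,
* slow cosine drift (the first three discrete-cosine components, random
  per-voxel weights), and
* AR(1) noise (coefficient 0.3) plus white noise with marginal SD
  `noise_sd`.

The drift components deliberately lie inside the span of the GLM's
high-pass cosine basis, which makes noise-free beta recovery exact and keeps
the drift a pure nuisance.

The synthetic ROI atlas stands in for probabilistically mapped retinotopy:
three adjacent area slabs (V1, V2, V3) each holding three concentric
eccentricity rings (fovea innermost), plus auditory-cortex and motor-cortex
control boxes. All extents scale with the grid, so a 24³ grid gives a
roughly thousand-voxel early visual cortex while a 14³ grid gives a compact
~200-voxel one for fast experiments.

### What the defaults mean and how they were chosen

Discriminability `d` is a per-voxel quantity; multivariate separability
accumulates over voxels, so realistic values are small. The defaults were
calibrated once, with a pilot grid search on the 24³ atlas, to land the
group-mean three-class accuracies on the levels the modelled study reports:
blind-like cohort — early visual cortex ≈ 0.62–0.66 with a clear
fovea < periphery < far-periphery gradient (`d` = 0.03 / 0.048 / 0.066),
auditory cortex near ceiling (`d` = 0.25), motor cortex at chance (`d` = 0);
sighted-like cohort — EVC ≈ 0.41 (`d` = 0.015 / 0.025 / 0.036) with a
slightly stronger auditory cortex (`d` = 0.35). They were fixed after that
pilot and are not tuned per analysis.

What the generator does *not* emulate: scanner artefacts (motion, spikes,
distortion), spatial autocorrelation of the noise, cortical geometry,
physiological nuisance, inter-subject anatomical variability. Passing tests
therefore demonstrate the correctness and calibration of the *procedures*
under a known generative model, not performance on real scanner data.

## GLM stage

Single-block betas use a least-squares-all scheme: one HRF-convolved boxcar
regressor per block (18 for a standard run), cosine high-pass nuisance
columns up to a 128 s cutoff (configurable; the filter is stated in the
modelled protocol, its cutoff is not), and an intercept. Ordinary least
squares per voxel; only point estimates feed the decoder, so no
autocorrelation correction is applied. The univariate sound-versus-rest path
is separate: it smooths (6 mm FWHM Gaussian, converted to voxels via the
header voxel size) before fitting a condition-level model; the multivariate
path is never smoothed.

## Decoding stage

Within an ROI, features are the in-mask block betas. For each held-out run
(leave-one-run-out), per-voxel means and SDs are estimated on the training
runs only and applied to both sides; zero-variance training voxels keep SD 1
rather than being dropped, preserving dimensionality across folds. Each
unordered pair of sounds gets a linear SVM (libsvm via `e1071`, cost 1, no
further scaling — the cited toolbox's defaults; no hyperparameter search).

Two accuracy scales coexist and are both reported:

* the fold × pair table of binary accuracies (chance 0.5), whose grand mean
  is `mean_pairwise_accuracy`;
* the primary `mean_accuracy`: three-class accuracy from one-vs-one voting
  over all held-out exemplars (chance one-out-of-three, the scale on which
  group results are reported). Voting ties receive fractional credit — the
  expectation of a random tie-break — keeping the statistic deterministic;
  the confusion matrix uses an explicitly seeded random tie-break instead,
  since it needs integer counts.

## Non-parametric inference

Permutation nulls shuffle condition labels independently within each run
(preserving per-run balance and the run structure that makes leave-one-run-out
exchangeable) and re-run the full cross-validation per permutation; only the
label-independent fold normalisation is reused. The p convention is
`max(#{null ≥ real}, 1) / n_perm`, which yields the floor 0.001 at 1000
permutations. Group p-values compare the mean real accuracy against the
index-wise mean of the subjects' null distributions, which requires (and
this package makes explicit via `perm_schedule()`) a shared permutation
indexing. The single-threshold (max-statistic) correction for the V1/V2/V3
family takes the per-permutation maximum of the mean null across ROIs.
Eccentricity ROIs are corrected with Benjamini–Hochberg FDR; the bootstrap
robustness check resamples subjects with replacement (10 000 samples,
percentile CI, one-sided p against chance).

A note on calibration at small scale: cross-validated accuracy under
realistic (temporally correlated) noise has a small negative bias relative
to nominal chance, a well-known property of CV with dependent exemplars. The
permutation machinery is immune to this because the null distribution
inherits the same bias; calibration tests therefore check uniformity of
permutation p-values and closeness of mean accuracy to chance within
simulation error at study scale.

## Group statistics

The Results-stage statistics are implemented as the modelled study reports
them: Mann-Whitney U with midranks, reporting `min(U_A, U_B)`, exact by
enumeration for small untied samples, normal approximation with tie
correction otherwise; a two-way repeated-measures ANOVA (area ×
eccentricity) with partial eta squared `SS_effect / (SS_effect + SS_error)`
and no sphericity correction (reproducing the uncorrected degrees of freedom
convention); a linear eccentricity contrast with weights (−1, 0, +1) applied
to each subject's area-averaged eccentricity means and tested as a
one-sample F on `(1, n − 1)` degrees of freedom; a mixed ANOVA adding the
group factor (tested against between-subject error; sequential decomposition
matching `aov`, valid for unequal group sizes with balanced within-subject
cells); the Friedman test with tie correction; Wilcoxon signed-rank with
zero-dropping and exact enumeration up to n = 15; and the bespoke
non-parametric interaction test — per-subject AC − EVC accuracy differences
compared between groups by Mann-Whitney — which sidesteps ceiling effects in
auditory cortex. Each rank test is verified in the test suite against an
independent oracle (`wilcox.test`, `friedman.test`, brute-force
enumeration); the ANOVAs are verified against `aov` to 1e-8 and satisfy the
sum-of-squares partition identity on every input.

## Searchlight stage

The searchlight is a cube (side 7, 343 voxels, by default) clipped at volume
and mask borders rather than skipping border centres; each centre's
neighbourhood is decoded with exactly the ROI scheme, so a searchlight value
equals `decode_loro()` on that neighbourhood (asserted in the tests).
Because the z-scoring is per voxel, fold normalisation is computed once over
the whole mask — an exact optimisation, not an approximation.

Group maps versus chance use a per-voxel one-sample t of accuracy − 1/3 (the
parametric group statistic inside the original volume tool is not stated;
this choice is documented as ours), thresholded voxelwise (p < 0.001) with
face-connectivity clusters corrected by a Monte-Carlo extent threshold:
smoothness-matched Gaussian noise volumes are thresholded and the
(1 − alpha) quantile of their maximum cluster size gives `k_min`. Noise
smoothness defaults to a gradient-based FWHM estimate from the residual
maps. This is a functional re-implementation of cluster-level threshold
estimation, not a bit-compatible port of any proprietary tool. Between-group
maps use a two-sample t (or a group + covariate linear model when a
univariate covariate is supplied), signed so positive means the first group
decodes better, with positive and negative cluster tables.

The sign-permutation group model computes a pseudo-t whose variance volume
is Gaussian-smoothed (2 mm FWHM default) before forming the standard error;
the null flips the sign of whole subject maps. With n subjects only 2^n
distinct flips exist, so when 2^n is smaller than the requested 10 000 the
enumeration is exhaustive (logged). The cluster-forming threshold is the
upper quantile of the pooled permutation pseudo-t distribution at the stated
voxelwise p (0.005), and cluster familywise error comes from the permutation
distribution of maximum cluster size.

## Numerical and design choices

* Voxel indices are reported 0-based in cluster tables; volumes are written
  with an identity-scaled affine; event onsets are seconds from the first
  retained volume.
* Gaussian smoothing uses a separable kernel truncated at 3 SD with edge
  renormalisation, so constant images are preserved exactly.
* Degenerate statistics are flagged, never emitted as infinities: zero
  between-subject variance in group maps, zero error sums of squares in the
  ANOVAs (e.g. noiseless gradients), all-zero difference vectors in the
  signed-rank test.
* All seed-taking functions restore the caller's RNG state, so nested
  seeded computations (e.g. a seeded tie-break inside a permutation loop)
  cannot silently couple independent simulations.
* Rejection sampling for the no-immediate-repeat block order draws uniformly
  from the valid sequences; infeasible constraints (one condition, two or
  more repetitions) are rejected explicitly.
* Where both a family of eccentricity ROIs and the V1/V2/V3 single-threshold
  family exist, the corrected family membership is configurable; the default
  follows the quoted V1/V2/V3 family.

## Problem sizes used by the tests and the acceptance script

The suite runs on compact grids (12³–14³ atlases, ~200-voxel EVC, 2–4 runs)
and reduced replicate counts (e.g. 200 permutation-uniformity replicates at
200 permutations, 20 group-difference simulations on the short design) —
sizes chosen so the full statistical behaviour (calibration, FWER control,
power, spatial specificity) is exercised at desk scale. The familywise-error
check of the max-statistic correction draws exchangeable accuracy vectors
directly rather than re-running 200 full decoding pipelines: the correction
consumes only accuracy vectors, and its decode-facing path is covered by the
permutation-uniformity check. The acceptance script regenerates a
strong-signal 8-subject cohort and reruns the full GLM → decoding →
1000-permutation group test on a ~200-voxel EVC mask.

## Known limitations

* Volume-space only; no surface geometry, no anatomical alignment.
* The simulator's noise is spatially white; spatial smoothness enters only
  through the explicit smoothing steps, so Monte-Carlo extent thresholds on
  simulated cohorts are conservative relative to smoothed real data.
* No motion/physiological nuisance modelling; the GLM estimates are plain
  OLS point estimates.
* Exact rank tests switch to normal approximations outside their enumeration
  ranges; tie-heavy data rely on the midrank corrections.
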