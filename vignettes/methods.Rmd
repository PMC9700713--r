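---
title: "Methods: model-based single-trial EEG analysis with hgfmmn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based single-trial EEG analysis with hgfmmn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling assumptions, parameter choices, and
numerical decisions behind `hgfmmn`. It is the design record for the
package; the README shows a worked example.

## The analysis in one paragraph

A listener hears a long sequence of standard and rare deviant tones. A
three-level hierarchical Gaussian filter (HGF) for binary inputs, fitted as
a Bayes-optimal learner to the tone sequence, yields trial-by-trial belief
trajectories: precision-weighted prediction errors (pwPEs) about tone
identity (`eps2`) and about environmental volatility (`eps3`), and the
uncertainties at each level. Those trajectories are used as single-trial
regressors for the EEG: per subject, epoch amplitudes are projected onto a
2-D scalp lattice and stacked over peristimulus time, spatially smoothed,
and regressed voxel-wise on one z-scored trajectory. Subject-level slope
maps enter group-level F tests with permutation-based family-wise error
(FWE) control at cluster and peak level, plus an ANCOVA of slopes against
symptom severity in the clinical group.

## Generative model and update equations

Level 1 is the binary tone, level 2 a continuous tendency `mu2` with
`p(u = 1) = logistic(mu2)`, level 3 a volatility state `mu3` controlling
the level-2 random-walk variance `exp(kappa * mu3 + omega2)`; level 3
itself diffuses with variance `exp(omega3)`. Filtering uses the standard
variational one-step updates under a Laplace (Gaussian) posterior
approximation; the closed forms implemented in `hgf_predict()` /
`hgf_update()` are re-derived in the package tests against an independent
scalar transcription and verified to `1e-10`.

Non-obvious numerical decisions:

* The level-2 posterior precision is `pihat2 + sigma1hat`, where
  `sigma1hat = muhat1 * (1 - muhat1)` is the Fisher information of the
  Bernoulli likelihood at the predicted rate. This follows from the
  Laplace approximation; it is a precision *sum*, not a variance sum.
* Admissibility: parameter/state combinations that drive the level-3
  posterior precision non-positive raise a structured condition
  (`hgf_numerical_error`, carrying the trial index). During fitting these
  are converted to an `Inf` surprise sentinel, never `NaN`, so the
  optimizer treats them as infinitely bad rather than silently continuing.
* Surprise is the negative log predictive probability of the observed
  tones (nats by default, bits on request), accumulated over the sequence.

`hgf_fit_bayes_optimal()` maximizes the penalized log score (surprise plus
Gaussian priors `omega2 ~ N(-3, 16)`, `omega3 ~ N(-6, 16)`), with
Nelder-Mead restarts from five fixed starting points. The fit is accepted
against a coarse grid-search oracle in the tests: the optimizer objective
must not exceed the grid minimum by more than 0.01 nats.

The default regressor for group analysis is the *signed* level-2 pwPE. A
rectified (absolute-value) variant is available (`rectify_pwpe = TRUE` in
`hgf_filter()`) because reasonable analyses differ here; the sign
convention is an explicit option rather than a hidden choice.

## Synthetic data generator

No patient EEG ships with the package; `gen_subject_eeg()` and
`gen_cohort()` emulate the study conditions so every stage can be
exercised at realistic scale. Defaults *are* the study conditions:

* Paradigm: 1830 tones, 10% deviants, 500 ms onset asynchrony, 500 Hz
  sampling, epochs -100..400 ms (251 samples), 32-channel modified 10-20
  montage plus a vertical EOG channel. Deviants are i.i.d. Bernoulli by
  default (`min_gap` can enforce standards after each deviant); true
  experimental sequences are typically pseudorandomized, which the
  generator deliberately does not imitate beyond the optional gap.
* Cohort: 23 healthy controls (HC) plus 31 clinical high-risk (CHR)
  subjects with SIPS positive-subscale totals drawn from N(10.5, 3.6^2),
  clipped at zero.
* Noise: per-channel AR(1) over time (`ar1 = 0.8`, stationary start) with
  spatially correlated innovations (Gaussian kernel over inter-electrode
  distance, 40 mm length scale), 5 uV marginal SD, a per-trial DC drift
  (2 uV SD), and half-cosine 150 ms blinks (400 uV on the EOG, 40%
  crosstalk on Fp1/Fp2) at a 5% trial rate, logged as ground truth.
* Planted effects: for chosen channels and a time window, the amplitude
  `amplitude * subject_scale * z(regressor)` is added per trial. A
  rectangular (top-hat) plant is used on purpose: recovery tests can then
  reason about exact window overlap instead of a soft blur.
* Symptom linkage: CHR subjects receive
  `subject_scale = 1 + effect_link * z(SIPS positive)`, so an ANCOVA on
  the true covariate has a known positive slope.

What the generator does **not** emulate: 1/f background spectra, alpha
rhythms, muscle or line noise, non-stationary artifacts, or realistic ERP
waveshapes. It is a test harness for the statistical pipeline, not a
forward model of EEG physics.

## Preprocessing

* Band-pass 0.5-30 Hz as a cascade of order-4 Butterworth high- and
  low-pass sections applied forward-backward (zero phase). A single
  band-pass design at a normalized low corner of 0.002 is numerically
  fragile; the cascade is stable and is verified against pass/stop-band
  attenuation targets in the tests.
* Blink handling: EOG excursions beyond 250 uV, padded by 100 ms and
  merged, mark intervals; epochs overlapping an interval are rejected
  (reason `"blink"`). On epoched data `reject_blinks()` applies the same
  threshold per epoch.
* Amplitude rule: epochs with any *good scalp-channel* sample exceeding
  100 uV absolute are rejected. EOG channels never trigger it.
* Channel rule: channels artefactual in strictly more than 20% of trials
  are flagged bad and replaced by inverse-distance-weighted interpolation
  (power 2) from the remaining good scalp channels; trial rejection is
  then recomputed over good channels only. Fewer than four good scalp
  channels is an error, not a silent degradation.
* Bookkeeping: every trial is accounted for exactly once (kept, blink,
  amplitude, or edge-dropped), and both rejection operators are
  idempotent - re-running them changes nothing.

## Scalp-by-time volumes and the first-level GLM

Channel amplitudes are projected to a 32 x 32 spatial grid (voxel 4.25 mm
x 5.38 mm) by piecewise-linear (Delaunay) interpolation, with out-of-hull
voxels masked; time bins are 2 ms over 100-400 ms. Because linear
interpolation is a linear map of channel values, the projector is
precomputed once as a (masked-voxels x channels) matrix, and all trials
are projected in a single matrix multiply.

Spatial smoothing uses a separable Gaussian (FWHM 16 x 16 mm, none along
time), renormalized inside the mask so border voxels do not leak mass to
the outside; an additive correction restores each volume's masked mean
exactly, so smoothing never shifts a map's overall level. The first-level
fit is ordinary least squares on `[1, z(regressor)]`, vectorized over all
voxels with the residual sum of squares computed via
`y'y - b'X'y` (verified against `lm()`); each regressor gets its own GLM,
rather than one multi-column design, so slope maps stay interpretable and
collinearity between trajectories is not silently partialled.

## Group inference

`one_sample_F()` tests the group-mean slope (F = t^2, df (1, n-1));
`group_difference()` compares groups with an unpaired pooled-variance t.
The analysis protocol this design follows describes a "paired t-test" for
a 23-vs-31 comparison, which cannot be taken literally; the implemented
test and the verbatim wording are both recorded in the result's
provenance and the run manifest rather than guessing intent.
`ancova_map()` tests a covariate slope with optional nuisance columns.

FWE control is by max-statistic permutation rather than random-field
theory: sign flipping (one-sample), group-label permutation (two-sample),
and Freedman-Lane residual permutation (ANCOVA). Suprathreshold voxels at
the cluster-defining threshold (`qf(1 - cdt_p, df1, df2)`, default
`cdt_p = 0.001`) are labelled by face connectivity (6; 18/26 available)
in compiled code, and both cluster extent and cluster peak are referred
to their permutation max null; `p = (1 + #{null >= obs}) / (n_perm + 1)`,
so p-values are never exactly zero. An empty cluster table is a valid,
explicitly reported outcome. Zero-variance voxels receive `+Inf` F
sentinels that count as suprathreshold; this errs toward flagging
degenerate data loudly.

Effect sizes use the standard conversion `eta2_p = F df1 / (F df1 + df2)`,
`f2 = eta2_p / (1 - eta2_p)`. Note `cohen_f2(29, 1, 29)` is exactly 1.0;
published analyses sometimes print materially smaller f^2 for similar F
and df, so printed effect sizes from other sources are not treated as
checkable targets by this package.

## Pipeline, provenance, determinism

A single master seed drives everything; per-subject and per-stage seeds
derive as `(seed * 10007 + k) mod (2^31 - 1)`. Each stage writes a
manifest with the config, its hash, package version, and MD5 digests of
every output file, so identical config + seed reproduces byte-identical
data files. Configs are YAML or JSON with unknown top-level keys rejected.
Epoch sets are interchanged between the simulate and run stages as
serialized R objects (`.rds`), a run-time artifact format; tone sequences,
trajectories, cluster tables, and rejection logs are TSV; ground truth
and manifests are JSON. A BrainVision reader (`read_brainvision()`,
multiplexed `IEEE_FLOAT_32`/`INT_16`) covers real-data ingestion; EDF
support is out of scope.

The command-line front end (`inst/cli/hgfmmn.R`) exposes `simulate`,
`hgf`, `run`, and `report`. The preprocessing, first-level and group
stages run inside `run`: exposing each as a standalone subcommand would
require a stable on-disk interchange format for epoch sets and beta maps,
which the run-time `.rds` artifacts are deliberately not.

## Desk-scale problem sizes

The full study geometry (54 subjects x 1830 trials x 32 x 32 x 151
voxels, 1000 permutations) is what the defaults describe, but package
tests and the acceptance script run scaled-down instances chosen a
priori for statistical power at desk scale: 6-8 subjects per group,
250-400 trials, a 12 x 12 x 4 ms grid, and 150-500 permutations.
Calibration of the family-wise error rate is checked on group-level null
slope maps drawn directly as Gaussian noise (the global null implies
zero-mean first-level slopes; what is under test there is the group-level
permutation machinery, not the generator).

## Limitations

* The generator's noise model is Gaussian AR(1); heavy-tailed artifacts
  would stress the amplitude rule differently.
* Piecewise-linear projection is not spline interpolation; maps differ
  near the convex hull boundary relative to spherical-spline packages.
* Permutation inference with very small groups has a coarse p-value
  floor (2^-n distinct sign patterns for n subjects).
* The HGF filter runs trial-sequentially in R; fitting very many long
  sequences is linear in trials x optimizer evaluations.
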