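---
title: "Decoding real-life self-control from preference-decision fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding real-life self-control from preference-decision fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdecode)
```

## The scientific problem

Laboratory measures of self-control and self-control in daily life are
measured on very different footings. In the design this package implements,
daily-life self-control comes from ecological momentary assessment (EMA):
smartphone alarms (up to 56 per subject over a week) prompt a short
questionnaire — was there a desire in the past hour, was it in conflict
with a superordinate goal, and was the desired behaviour enacted anyway?
A subject's outcome is the probability of a **self-control failure**,

\[
y_i \;=\; \frac{\#\{\text{enacted conflict-laden desires}\}_i}
               {\#\{\text{conflict-laden desires}\}_i},
\]

which is undefined (and excludes the subject) when no conflicts are
reported.

The laboratory side is a preference decision task under fMRI: subjects
decide, for everyday activities, whether they would enact them (four-point
scale, recoded −2/−1/+1/+2), and later rate each activity's anticipated
short- and long-term consequences on a six-point scale recoded to
\(\{-3,\dots,-1,1,\dots,3\}\) (no neutral point). An item is **divergent**
when the two ratings have opposite signs. Crossing the rating sign pattern
with accept/decline yields eight per-trial categories; the two
long-term-consistent categories (declining a "fun now, bad later" option;
accepting a "painful now, good later" option) and the two
short-term-consistent ones are collapsed into LONG and SHORT decision sets.

The pipeline then asks two questions. First, *where* does BOLD activity
differ between LONG and SHORT decisions (univariate group analysis with
random-field-theory FWE correction)? Second, can the multivariate activity
pattern in those regions *predict each individual's* real-life failure
probability (L1-regularised logistic decoding under nested
leave-one-subject-out cross-validation, significance by permutation)?

## Pipeline stages and the models behind them

### First-level GLM

Each retained subject's voxel time series is modelled by ordinary least
squares on a design with: one boxcar regressor per nonempty trial category
(stimulus duration 3.5 s) convolved with the canonical double-gamma HRF
(peak delay 6 s, undershoot delay 16 s, dispersions 1, undershoot ratio
1/6, 32-s support, built at 16 microtime bins per TR and sampled at frame
times); a missed-trial regressor; six motion series; a constant; and
discrete-cosine drift columns for periods at or above the 128-s high-pass
cutoff. Events are modelled as 3.5-s boxcars (the item stays on screen for
the full stimulation period); the duration is a configuration knob.

The long > short contrast averages the available condition estimates
within each collapsed side before subtracting, so each side's weights sum
to one even when one member of a pair had no trials (the survivor then
carries weight 1, and this is recorded). Collapsing at the contrast level
is exactly equivalent under OLS to re-fitting a two-condition model, and
preserves the full eight-condition model.

OLS is the default noise model; an AR(1) Cochrane–Orcutt mode is available
(`prewhiten = "ar1"`) and is testable because the simulator generates
AR(1) noise.

### Group inference and ROI definition

Contrast images are within-subject differences, so the second-level
"paired t-test" is the one-sample t on the contrast maps, df = N − 1.
Smoothness is estimated from the variance of spatial derivatives of the
voxelwise-normalised residual maps (Kiebel/Worsley estimator); resel
counts come from lattice counting of in-mask vertices, edges, faces and
cubes. Voxel-level FWE uses the expected Euler characteristic of a
t-field, \(p_{FWE}(t)=\min(1,\sum_{d=0}^3 R_d\,\rho_d(t))\), with the
critical threshold found by monotone root-finding. Clusters are formed at
uncorrected p < 0.001 with 18-connectivity (the SPM convention; 6 and 26
are available) and kept when at least 270 mm³ (10 voxels at 3-mm
isotropic). Retained clusters are ordered by peak t with lexicographic
tie-breaking, so extraction is independent of discovery order.

The decoding ROI is the union of retained whole clusters
(`roi_mode = "all_clusters"`), matching the use of second-level clusters
as ROIs; a stricter mode keeps only clusters whose peaks survive FWE.

### Decoding

Features are the contrast-map values at ROI voxels, one row per subject in
id-sorted order. The decoder is L1-regularised logistic regression on the
fractional outcomes: it minimises mean binomial deviance plus
\(\lambda\sum_j|\beta_j|\) with an unpenalised intercept (the standard
lasso-GLM objective; fitted via glmnet on two-column fractional responses with
internal standardisation disabled). Keeping the estimator binomial keeps
predictions inside (0, 1), which is what makes an RMSE around 0.3 on a
probability scale meaningful.

The penalty is tuned over the half-power grid
\(\{2^{-8},2^{-8.5},\dots,2^{-13.5}\}\) by a nested leave-one-subject-out
loop run inside every outer training set; the inner criterion is held-out
binomial deviance (held-out squared error is selectable), ties resolve to
the largest (sparsest) penalty. Feature standardisation is on by default
and always computed inside the training rows only — the leakage contract
("changing the left-out subject's outcome never changes its prediction")
is tested explicitly. Performance is the Pearson correlation and RMSE
between cross-validated predictions and observed outcomes; significance is
the fraction of permutations of the predictions whose correlation with the
observed outcomes is at least the observed correlation (with the
\((b+1)/(m+1)\) estimator reported alongside, and a "< 1/n_perm" label
when no permutation reaches the observed value).

Two feature-selection regimes are exposed. `mode = "paper"` defines the
ROI once from the full sample — this reuses each test subject's data for
feature selection and is therefore optimistic — a recognised caveat of
circular feature selection. `mode = "honest"` re-derives the ROI inside every outer
fold from the training subjects only; folds whose training sample yields
no cluster fall back to the training-mean prediction.

A seeded, outcome-stratified k-fold variant (`kfold_predict()`) reproduces
leave-one-subject-out exactly at k = n. Per-ROI univariate means and
per-ROI decoding (`univariate_baseline()`) provide the post-hoc
comparisons.

## What the synthetic-data generator emulates

The generator reproduces the study's fixed design constants: TR 2 s,
3.5-s stimuli, ISIs jittered over {5, 6, 7} s, 40 items × 3 repetitions
(120 trials), up to 56 alarms, and the EMA stage probabilities implied by
the published cohort descriptives (alarm response 0.785; desire given
answered 0.724 = 31.85/43.97; conflict given desire 0.365; baseline
failure probability 0.531). Item divergence defaults to 0.5 (observed:
51.53% of trials) and the per-trial miss probability to 0.02 (observed
mean 2.59 of 120).

The forward BOLD model mirrors the analysis GLM exactly — per voxel, class
effects times boxcar⊛HRF regressors — plus spatially varying slow cosine
drift, six motion nuisance series with small voxel loadings, and AR(1)
Gaussian noise; the summed series is smoothed with an 8-mm FWHM Gaussian
(the study's kernel), emulating smoothing of preprocessed images. Because
the forward model matches the GLM, noise-free recovery of the planted
effects is exact by construction, which the tests exploit as an oracle.

Subject heterogeneity has three parts. (1) Inside three planted
parietal-like spherical ROIs (9-mm radius by default), subject `i`'s true
long-minus-short pattern is `effect_size + subject_amp_sd·e_i +
pattern_sd·g_iv`, with the amplitude disturbance `e_i` loading negatively
on latent self-control (so better self-controlled subjects express the
pattern less and make more long-term-consistent lab choices — this single
latent channel produces the observed positive correlation between
short-term decision counts and real-life failures). (2) A fixed
positive-mean random weight vector over ROI voxels turns the pattern into
a scalar "pattern expression" whose standardised value enters the failure
probability through `plogis(qlogis(0.531) + coupling_b · z)`; that gives
the decoder a recoverable multivariate target. (3) Every subject also gets
an idiosyncratic mean-zero long-minus-short background field over the
whole grid (`subject_field_sd`, white at contrast level, smoothed with
everything else). Real contrast maps show exactly this kind of
between-subject variance outside true effects; without it the group
t-field has essentially zero between-subject noise off-ROI, suprathreshold
regions balloon far beyond the planted spheres, and the RFT machinery has
nothing resembling its stationary-smooth-noise assumptions to work with.

### Calibration of the free amplitudes

The study gives no effect size for the long > short contrast; its only
anchor is a peak t of 4.71 at N = 281. The defaults
(`effect_size = 0.4`, `subject_amp_sd = 0.35`, `subject_field_sd = 1.6`
pre-smoothing ≈ 0.2 at contrast scale, `noise_sd = 3`) were set once, by a
small variance calculation plus a handful of desk-scale runs, so that a
40-subject, 16³-grid study lands its group peak t in the mid-single
digits (typically 5–9) with clusters that track the planted spheres
(Dice ≈ 0.65–0.8) rather than engulfing the grid. `coupling_b = 1`
produces failure probabilities spanning roughly 0.2–0.85 around the
observed 53.1% base rate.

### What the generator does *not* emulate

No anatomy, no physiological noise, no actual head motion (only additive
nuisance loadings), no slice-timing effects, no nonstationary smoothness,
and EMA items beyond the desire→conflict→enactment chain are filled in
uniformly. Passing tests therefore demonstrate that the *analysis
machinery* is correct and calibrated under its own assumptions — not that
those assumptions hold in any particular real dataset.

## Numerical choices and degenerate inputs

- Child seeds: every stochastic stage derives its seed from
  `(master seed, stage name, subject)`, so stages re-run identically in
  isolation; all seeds stay below 2³¹.
- Zero-variance voxels in the group t-map get signed infinite t (zero t
  when the mean is also zero) and are flagged rather than propagated as
  NaN.
- The expected-EC sum is clamped to [0, 1] and the FWE threshold is
  root-found only beyond the mode of the EC curve, where it is monotone.
- Lambda ties in the nested loop resolve to the largest penalty; inner
  loops require at least 3 training subjects, below which the sparsest
  grid value is used (relevant only for extreme k-fold settings).
- glmnet is called with a descending lambda path and a tight convergence
  threshold (1e-10); the unpenalised limit matches an independent
  Newton–Raphson MLE to well below the 1e-5 test tolerance.
- Empty conditions are dropped from the design (and recorded); duplicate
  event onsets, rank-deficient designs (with the collinear column named),
  NaNs in data, constant outcomes, and empty cluster tables all raise
  informative errors rather than producing silent results.

## Problem sizes used by the test and acceptance runs

Unit and property tests run on miniature studies (6–14 subjects, 8³–10³
grids, 6–12 items) where every stage is still exercised end to end. The
statistical suites use: 500 replicates for the empirical FWE rate of the
RFT threshold (16³ grid, 30 maps, FWHM 3 voxels) and for the
permutation-test rejection rate (n_perm = 2000); 20 replicate studies of
40 subjects on a 16³ grid (12 items × 2 repetitions) for ROI recovery
(Dice ≥ 0.5 against ground truth); and 20 + 20 coupled/null decode-stage
replicates at n = 40 on simulator ground-truth patterns with
contrast-scale estimation noise and EMA-observed outcomes. The
`scripts/acceptance.R` run executes one full 24-subject desk-scale study
at the complete 120-trial paradigm with 10,000 permutations.

Two calibration notes, measured while validating (not asserted anywhere
tests do not recompute them): voxel-level RFT on t-fields at df ≈ 29 and
FWHM 3 voxels is intrinsically conservative — the empirical family-wise
error of the nominal 5% threshold sits near 2%, because the
continuum-based expected Euler characteristic overpredicts excursion
counts on lattice data with heavy-tailed t-fields (at df 100 the same
machinery measures ≈ 3.5%). And honest-mode decoding is expected to score
at or below paper-mode on average; at desk-scale sample sizes the
difference is well inside fold noise, so the tests assert the mechanism
(per-fold ROIs, differing predictions) rather than a noisy ordering.

## Known limitations

- The within-ROI multivariate pattern (`pattern_sd`) is largely blurred
  out by the 8-mm kernel at 3-mm voxels, so decoding signal at desk scale
  is carried mostly by the subjects' shared-amplitude component. A
  generator with spatially structured (smooth) within-ROI patterns would
  preserve more genuinely multivariate signal.
- Smoothness estimation uses second-level residual maps; SPM estimates it
  from first-level residuals. Both are standard; at matched FWHM they
  agree to within the estimator's own bias (~5–7% overestimation on a
  discrete lattice).
- The permutation test permutes predictions against outcomes after
  cross-validation, matching the original procedure; it tests exchange-
  ability of the pairing, not of the full training process.
- `n_perm = 1e6` (the printed default) is exact only in expectation; the
  desk-scale pipeline default uses 10,000 draws and reports the
  `(b+1)/(m+1)` estimator alongside the raw fraction.
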