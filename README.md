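# scdecode

Brain decoding of real-life self-control from preference-decision fMRI.

## The problem

Does brain activity during laboratory decisions generalise to self-control
in daily life? The design this package implements combines three data
streams per subject:

- **EMA** (ecological momentary assessment): up to 56 smartphone alarms
  over a week ask whether a desire occurred, whether it conflicted with a
  superordinate goal, and whether it was enacted. The outcome is each
  subject's probability of a *self-control failure*,
  `y = failures / conflicts`.
- **Behaviour**: 120 preference decisions (40 items x 3 repetitions,
  accept/decline on a four-point scale) plus six-point ratings of each
  item's anticipated short- and long-term consequences (recoded
  -3..-1, 1..3). An item is *divergent* when the two ratings disagree in
  sign; crossing sign pattern with accept/decline yields eight trial
  categories that collapse into decisions in line with **long-term** vs
  **short-term** consequences.
- **fMRI**: first-level GLMs (canonical double-gamma HRF, 3.5-s boxcars,
  128-s cosine high-pass, motion + missed-trial nuisance) produce each
  subject's `long > short` contrast map. A second-level one-sample t-field
  with random-field-theory voxel-level FWE correction and a 270 mm^3
  cluster-extent rule defines parietal ROIs. An L1-regularised logistic
  decoder (penalty tuned over `{2^-8, 2^-8.5, ..., 2^-13.5}` by nested
  leave-one-subject-out cross-validation) predicts `y` from the ROI
  activity patterns; significance comes from permuting predictions
  against outcomes (`p = #{r_null >= r_obs} / n_perm`).

A first-class synthetic-data module generates complete multi-subject
studies (EMA records, ratings, decisions with onsets, 4-D BOLD with
planted effects, ground truth), so the whole pipeline is testable and its
parameter recovery demonstrable without any external data.

## Worked example

A desk-scale simulated study (24 subjects, 16^3 grid at 3 mm, the full
120-trial paradigm; about two minutes on one CPU):

```r
library(scdecode)

cfg <- pipeline_config(
  sim = sim_config(n_subjects = 24, grid_dims = c(16, 16, 16), seed = 1),
  n_perm = 10000)
report <- run_pipeline(cfg)
report
#> Pipeline run (seed 1): 24/24 subjects retained, 3 cluster(s), peak t = 6.29
#>   ROI Dice vs truth = 0.72; decoding r = 0.276, RMSE = 0.324, permutation p = 0.0946

tidy(report$cluster_table)
#> # A tibble: 3 x 9
#>   cluster_id n_voxels size_mm3 peak_x peak_y peak_z peak_t peak_p_fwe
#> 1          1      105     2835     11      4     10   6.29     0.0114
#> 2          2       95     2565      5      3      9   5.62     0.0419
#> 3          3       90     2430      6     12      7   4.92     0.159

glance(report$decoding)
#> # A tibble: 1 x 4
#>       r  rmse     n median_lambda
#> 1 0.276 0.324    24       0.00391
```

Reading the output: the group stage found the three planted parietal-like
clusters (two of the three peaks survive voxel-level FWE at this small N;
ROI union overlaps ground truth at Dice 0.72). Decoding the failure
probability from the ROI patterns gives cross-validated r = 0.276 with
RMSE = 0.324 on the probability scale; at N = 24 the permutation test is
not yet significant (p = 0.095) — individual-level prediction of this
strength needs cohorts in the hundreds of subjects.

Useful pieces on their own:

```r
autoplot(report$decoding)        # predicted vs observed probabilities
plot_stat_slice(report$group_stat)  # axial slice of the group t-map

summarize_ema_cohort(records)    # per-subject EMA summaries from a TSV
classify_trials(trials, ratings) # eight-category trial classification
simulate_dataset(sim_config(), "out/")  # write a BIDS-like synthetic study
```

The methods vignette
(`vignettes/decoding-real-life-self-control.Rmd`) documents the models,
the generator's assumptions, calibration of the free amplitudes, and
numerical edge cases.

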