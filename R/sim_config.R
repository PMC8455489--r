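#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce the
#' study conditions of the motivating design wherever those are fixed by the
#' paradigm: TR 2 s, 3.5-s stimulus presentation, interstimulus intervals
#' jittered over 5/6/7 s, 40 items repeated 3 times (120 trials), up to 56
#' EMA alarms per subject, and EMA stage probabilities matching the observed
#' cohort descriptives (78.5% answered alarms, 72.4% of answered alarms with
#' a desire, 36.5% of desires conflict-laden, baseline failure probability
#' 53.1%). Quantities the paradigm does not fix (grid size, noise levels,
#' effect amplitude) default to desk-scale values documented in the methods
#' vignette.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param grid_dims Integer triple, voxel grid (each >= 8).
#' @param voxel_size_mm Isotropic voxel edge in mm.
#' @param tr_s Repetition time in seconds.
#' @param n_items,n_reps Items in the preference task and repetitions each.
#' @param stim_dur_s Stimulus (and modelled event) duration in seconds.
#' @param isi_choices_s Jittered interstimulus-interval choices in seconds.
#' @param roi_specs List of `list(center = c(i, j, k), radius_mm = r)` spheres
#'   carrying the planted long > short effect. `NULL` places three
#'   parietal-like spheres at fixed relative grid positions.
#' @param effect_size Planted long-minus-short contrast amplitude inside the
#'   ROIs (signal units of the BOLD simulation).
#' @param coupling_b Slope linking standardised ROI pattern expression to the
#'   logit of the subject's true self-control-failure probability.
#' @param noise_sd Scan-level Gaussian noise standard deviation.
#' @param ar1_rho Lag-1 autocorrelation of the scan noise, in `[0, 1)`.
#' @param drift_amp Amplitude of the low-frequency scanner drift.
#' @param n_alarms EMA alarms issued per subject.
#' @param p_respond,p_desire,p_conflict EMA stage probabilities: alarm
#'   answered; desire reported given answered; conflict given desire.
#' @param divergence_frac Expected fraction of items whose short- and
#'   long-term consequence ratings have opposite signs.
#' @param miss_prob Per-trial probability of a missed response.
#' @param smooth_fwhm_mm Gaussian smoothing kernel FWHM applied to the
#'   simulated BOLD (and therefore inherited by contrast maps).
#' @param subject_amp_sd Between-subject SD of the ROI effect amplitude.
#' @param subject_field_sd Voxelwise SD (before smoothing) of each
#'   subject's idiosyncratic long-minus-short background field, present
#'   everywhere and mean-zero across subjects; it supplies the
#'   between-subject variance real contrast maps show outside true effects.
#' @param pattern_sd Within-ROI voxelwise SD of each subject's true contrast
#'   pattern around their amplitude (the multivariate signal the decoder can
#'   exploit).
#' @param baseline_p_fail Population failure probability at zero pattern
#'   expression.
#' @param decision_slope Logistic slope of long-term-consistent choice on the
#'   subject's latent self-control.
#' @param seed Master seed; every stochastic stage derives a child seed from
#'   it so stages are individually reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 24,
                       grid_dims = c(24L, 24L, 24L),
                       voxel_size_mm = 3,
                       tr_s = 2,
                       n_items = 40,
                       n_reps = 3,
                       stim_dur_s = 3.5,
                       isi_choices_s = c(5, 6, 7),
                       roi_specs = NULL,
                       effect_size = 0.4,
                       coupling_b = 1.0,
                       noise_sd = 3.0,
                       ar1_rho = 0.3,
                       drift_amp = 1.0,
                       n_alarms = 56,
                       p_respond = 0.785,
                       p_desire = 0.724,
                       p_conflict = 0.365,
                       divergence_frac = 0.5,
                       miss_prob = 0.02,
                       smooth_fwhm_mm = 8,
                       subject_amp_sd = 0.35,
                       subject_field_sd = 1.6,
                       pattern_sd = 0.35,
                       baseline_p_fail = 0.531,
                       decision_slope = 1.5,
                       seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 8L)) {
    abort("`grid_dims` must be three integers, each >= 8.")
  }
  if (ar1_rho < 0 || ar1_rho >= 1) abort("`ar1_rho` must lie in [0, 1).")
  for (nm in c("p_respond", "p_desire", "p_conflict", "divergence_frac",
               "miss_prob", "baseline_p_fail")) {
    assert_prob(get(nm), nm)
  }
  assert_count(n_subjects, "n_subjects")
  assert_count(n_items, "n_items", min = 2L)
  assert_count(n_reps, "n_reps")
  assert_count(n_alarms, "n_alarms")
  if (voxel_size_mm <= 0 || tr_s <= 0 || stim_dur_s <= 0) {
    abort("`voxel_size_mm`, `tr_s` and `stim_dur_s` must be positive.")
  }
  if (any(isi_choices_s <= 0)) abort("`isi_choices_s` must be positive.")
  if (is.null(roi_specs)) roi_specs <- default_roi_specs(grid_dims)
  for (spec in roi_specs) {
    ctr <- spec$center
    rad_vox <- spec$radius_mm / voxel_size_mm
    if (any(ctr - rad_vox < 1) || any(ctr + rad_vox > grid_dims)) {
      abort("Each ROI sphere must lie fully inside the grid.")
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), grid_dims = grid_dims,
      voxel_size_mm = voxel_size_mm, tr_s = tr_s,
      n_items = as.integer(n_items), n_reps = as.integer(n_reps),
      stim_dur_s = stim_dur_s, isi_choices_s = isi_choices_s,
      roi_specs = roi_specs, effect_size = effect_size,
      coupling_b = coupling_b, noise_sd = noise_sd, ar1_rho = ar1_rho,
      drift_amp = drift_amp, n_alarms = as.integer(n_alarms),
      p_respond = p_respond, p_desire = p_desire, p_conflict = p_conflict,
      divergence_frac = divergence_frac, miss_prob = miss_prob,
      smooth_fwhm_mm = smooth_fwhm_mm, subject_amp_sd = subject_amp_sd,
      subject_field_sd = subject_field_sd,
      pattern_sd = pattern_sd, baseline_p_fail = baseline_p_fail,
      decision_slope = decision_slope, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Three parietal-like spheres at fixed relative grid positions: two lateral
# (angular-gyrus-like, left/right) and one medial posterior (precuneus-like).
default_roi_specs <- function(grid_dims) {
  rel <- list(c(0.25, 0.30, 0.65), c(0.75, 0.30, 0.65), c(0.50, 0.75, 0.45))
  lapply(rel, function(r) {
    list(center = pmax(4L, pmin(grid_dims - 3L, round(r * grid_dims))),
         radius_mm = 9)
  })
}

#' Build the boolean ROI mask for a configuration
#'
#' @param cfg A [sim_config()].
#' @return A logical array of dimension `cfg$grid_dims`, `TRUE` inside the
#'   union of the configured ROI spheres. Attribute `roi_id` holds an integer
#'   array labelling voxels by ROI (0 outside).
#' @export
roi_mask_from_config <- function(cfg) {
  d <- cfg$grid_dims
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  lab <- integer(nrow(idx))
  for (r in seq_along(cfg$roi_specs)) {
    spec <- cfg$roi_specs[[r]]
    dist_mm <- sqrt(colSums((t(idx) - spec$center)^2)) * cfg$voxel_size_mm
    lab[dist_mm <= spec$radius_mm] <- r
  }
  mask <- array(lab > 0L, dim = d)
  attr(mask, "roi_id") <- array(lab, dim = d)
  mask
}
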