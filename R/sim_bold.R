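# Dense one-axis Gaussian smoothing matrix, rows normalised so a constant
# volume stays constant near the edges.
gaussian_smooth_1d <- function(n, fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  if (sigma <= 1e-8) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  S <- exp(-d^2 / (2 * sigma^2))
  S / rowSums(S)
}

#' Smooth volumes with a separable 3-D Gaussian kernel
#'
#' @param x Either a 3-D array, a 4-D array (`x, y, z, t`), or an
#'   `n_voxels x m` matrix in array order (then `dims` is required).
#' @param fwhm_mm Kernel full width at half maximum in mm (0 = identity).
#' @param voxel_mm Isotropic voxel size in mm.
#' @param dims Grid dims when `x` is a matrix.
#' @return Object of the same shape as `x`.
#' @export
smooth_volume <- function(x, fwhm_mm, voxel_mm, dims = NULL) {
  as_matrix <- is.matrix(x)
  if (as_matrix) {
    m <- ncol(x)
    V <- array(x, dim = c(dims, m))
  } else if (length(dim(x)) == 3L) {
    dims <- dim(x)
    m <- 1L
    V <- array(x, dim = c(dims, 1L))
  } else {
    dims <- dim(x)[1:3]
    m <- dim(x)[4]
    V <- x
  }
  if (fwhm_mm > 0) {
    f <- fwhm_mm / voxel_mm
    for (ax in 1:3) {
      S <- gaussian_smooth_1d(dims[ax], f)
      perm <- c(ax, setdiff(1:3, ax), 4L)
      Vp <- aperm(V, perm)
      dp <- dim(Vp)
      Vp <- array(S %*% matrix(Vp, nrow = dims[ax]), dim = dp)
      V <- aperm(Vp, order(perm))
    }
  }
  if (as_matrix) {
    matrix(V, nrow = prod(dims), ncol = m)
  } else if (m == 1L && length(dim(x)) == 3L) {
    array(V, dim = dims)
  } else {
    V
  }
}

#' Draw the cohort ground truth
#'
#' Latent self-control per subject; a boolean ROI mask; each subject's true
#' long-condition contrast pattern over ROI voxels (population amplitude
#' `effect_size`, between-subject amplitude variation loading negatively on
#' latent self-control, plus voxelwise pattern heterogeneity); a fixed
#' positive-mean random weight vector over ROI voxels whose inner product
#' with the pattern defines the subject's "pattern expression"; and the
#' true failure probability
#' `plogis(qlogis(baseline_p_fail) + coupling_b * z(pattern expression))`.
#' Outside the ROI mask the true long and short effects are both zero.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `ground_truth`: `latent_self_control`,
#'   `roi_mask` (with `roi_id` attribute), `roi_voxels` (indices),
#'   `beta_long_roi` (`n_subjects x n_roi_voxels`), `weights`,
#'   `pattern_expression`, `true_p_fail`.
#' @export
make_ground_truth <- function(cfg) {
  set.seed(child_seed(cfg$seed, "ground_truth"))
  n <- cfg$n_subjects
  mask <- roi_mask_from_config(cfg)
  vox <- which(mask)
  latent <- rnorm(n)
  e <- -0.6 * latent + 0.8 * rnorm(n)
  amp <- cfg$effect_size + cfg$subject_amp_sd * e
  pattern <- matrix(rnorm(n * length(vox), sd = cfg$pattern_sd), nrow = n)
  beta_long <- sweep(pattern, 1, amp, "+")
  w <- 1 + 0.5 * rnorm(length(vox))
  s <- drop(beta_long %*% w) / length(vox)
  z <- if (n > 1 && sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, n)
  p_fail <- plogis(qlogis(cfg$baseline_p_fail) + cfg$coupling_b * z)
  structure(
    list(latent_self_control = latent, roi_mask = mask, roi_voxels = vox,
         beta_long_roi = beta_long, weights = w, pattern_expression = s,
         true_p_fail = p_fail),
    class = "ground_truth"
  )
}

# Expand one subject's true long/short effect into full volumes.
true_beta_volume <- function(gt, subject, which = c("long", "short")) {
  which <- match.arg(which)
  vol <- array(0, dim = dim(gt$roi_mask))
  if (which == "long") vol[gt$roi_voxels] <- gt$beta_long_roi[subject, ]
  vol
}

#' Simulate one subject's 4-D BOLD run
#'
#' Forward model mirroring the analysis GLM: per voxel the signal is the
#' sum over trial classes of the true class effect times the boxcar-
#' convolved canonical HRF, plus spatially varying low-frequency cosine
#' drift, six motion nuisance series with small voxel loadings, and AR(1)
#' Gaussian noise; the summed volume series is then smoothed with the
#' configured Gaussian kernel (emulating smoothing of preprocessed images).
#'
#' @param trials Classified trial tibble (from [classify_trials()]) with
#'   `onset_s`, `duration_s`, `trial_class`.
#' @param gt A [make_ground_truth()] object.
#' @param subject Subject index into `gt`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param n_scans Optional scan count; defaults to covering the last onset
#'   plus 32 s. An explicit value that falls short is an error.
#' @return List with `bold` (4-D array), `motion` (tibble, 6 columns),
#'   `n_scans`, `tr_s`.
#' @export
simulate_bold <- function(trials, gt, subject, cfg, seed, n_scans = NULL) {
  set.seed(seed)
  need_t <- max(trials$onset_s + trials$duration_s) + 32
  need_scans <- ceiling(need_t / cfg$tr_s)
  if (is.null(n_scans)) n_scans <- need_scans
  if (n_scans < need_scans) {
    abort("Scan length is shorter than the paradigm plus HRF decay.")
  }
  dims <- cfg$grid_dims
  n_vox <- prod(dims)

  events <- tibble(onset_s = trials$onset_s, duration_s = trials$duration_s,
                   condition = as.character(trials$trial_class))
  des <- build_design_matrix(events, motion = NULL, n_scans = n_scans,
                             tr_s = cfg$tr_s, hp_cutoff_s = Inf)
  X_task <- des$values[, des$task_columns, drop = FALSE]

  B <- matrix(0, nrow = ncol(X_task), ncol = n_vox)
  long_vec <- rnorm(n_vox, sd = cfg$subject_field_sd)
  long_vec[gt$roi_voxels] <- long_vec[gt$roi_voxels] +
    gt$beta_long_roi[subject, ]
  for (cn in intersect(c("LT_A", "LT_B"), colnames(X_task))) {
    B[match(cn, colnames(X_task)), ] <- long_vec
  }
  Y <- X_task %*% B

  # spatially varying slow cosine drift (periods >= two-thirds of the run)
  drift_basis <- dct_drift_basis(n_scans, cfg$tr_s,
                                 hp_cutoff_s = n_scans * cfg$tr_s * 2 / 3)
  if (ncol(drift_basis) && cfg$drift_amp > 0) {
    coefs <- matrix(rnorm(ncol(drift_basis) * n_vox, sd = cfg$drift_amp),
                    nrow = ncol(drift_basis))
    Y <- Y + drift_basis %*% coefs
  }

  motion <- matrix(apply(matrix(rnorm(n_scans * 6, sd = 0.02), n_scans), 2,
                         cumsum), n_scans)
  loadings <- matrix(rnorm(n_vox * 6, sd = 0.02), ncol = 6)
  Y <- Y + motion %*% t(loadings)

  if (cfg$noise_sd > 0) {
    innov <- matrix(rnorm(n_scans * n_vox,
                          sd = cfg$noise_sd * sqrt(1 - cfg$ar1_rho^2)),
                    n_scans)
    if (cfg$ar1_rho > 0) {
      for (tt in 2:n_scans) {
        innov[tt, ] <- innov[tt, ] + cfg$ar1_rho * innov[tt - 1L, ]
      }
    }
    Y <- Y + innov
  }

  Y <- t(smooth_volume(t(Y), cfg$smooth_fwhm_mm, cfg$voxel_size_mm,
                       dims = dims))
  list(bold = array(t(Y), dim = c(dims, n_scans)),
       motion = as_tibble(as.data.frame(motion),
                          .name_repair = ~ paste0("motion_", 1:6)),
       n_scans = n_scans, tr_s = cfg$tr_s)
}
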