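#' Pipeline configuration
#'
#' Bundles the simulation configuration with every analysis-stage option.
#' Analysis thresholds default to the headline values of the design:
#' cluster-forming p 0.001, 270 mm^3 extent, voxel-level FWE alpha 0.05,
#' 128-s high-pass cutoff, the half-power lambda grid, and one million
#' permutations.
#'
#' @param sim A [sim_config()].
#' @param cluster_p Cluster-forming uncorrected p threshold.
#' @param extent_mm3 Minimum cluster extent in mm^3.
#' @param fwe_alpha Voxel-level FWE level.
#' @param hp_cutoff_s High-pass cutoff period (s).
#' @param decoder A [decoder_config()].
#' @param n_perm Permutations for the significance test.
#' @param roi_mode `"all_clusters"` or `"fwe_peaks_only"`.
#' @param mode `"paper"` (ROIs from the full sample, as in the original
#'   analysis, which reuses test subjects for feature selection) or
#'   `"honest"` (ROIs re-derived inside every outer fold).
#' @param prewhiten First-level noise model, `"none"` or `"ar1"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            cluster_p = 0.001, extent_mm3 = 270,
                            fwe_alpha = 0.05, hp_cutoff_s = 128,
                            decoder = decoder_config(),
                            n_perm = 1e6,
                            roi_mode = "all_clusters",
                            mode = c("paper", "honest"),
                            prewhiten = "none") {
  mode <- match.arg(mode)
  structure(list(sim = sim, cluster_p = cluster_p, extent_mm3 = extent_mm3,
                 fwe_alpha = fwe_alpha, hp_cutoff_s = hp_cutoff_s,
                 decoder = decoder, n_perm = n_perm, roi_mode = roi_mode,
                 mode = mode, prewhiten = prewhiten),
            class = "pipeline_config")
}

# First-level analysis of one simulated subject: design, GLM, contrast.
first_level_contrast <- function(sub, cfg) {
  events <- tibble(onset_s = sub$trials$onset_s,
                   duration_s = sub$trials$duration_s,
                   condition = as.character(sub$trials$trial_class))
  des <- build_design_matrix(events, motion = as.matrix(sub$motion),
                             n_scans = sub$n_scans, tr_s = sub$tr_s,
                             hp_cutoff_s = cfg$hp_cutoff_s)
  fit <- fit_glm(sub$bold, des, prewhiten = cfg$prewhiten)
  compute_contrast(fit)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates the cohort from `cfg$sim`, applies the EMA and task exclusion
#' rules, fits the first-level GLMs and the long > short contrast per
#' retained subject, runs second-level inference (t-field, smoothness, RFT
#' voxel FWE, cluster extent rule) to define ROIs, decodes each subject's
#' real-life failure probability from the ROI patterns, and assesses the
#' prediction-outcome correlation by permutation. Halts with a stage-named
#' message if any stage empties the cohort or the ROI.
#'
#' @param cfg A [pipeline_config()].
#' @return Object of class `run_report`: exclusion logs, cluster table,
#'   decoding and permutation results, ground-truth comparisons (ROI Dice,
#'   correlation of true and observed failure probability), resolved
#'   config, package version and seed.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  sim <- cfg$sim
  gt <- make_ground_truth(sim)

  ema_summaries <- list()
  task_log <- list()
  subjects <- list()
  for (i in seq_len(sim$n_subjects)) {
    sub <- simulate_subject(sim, i, gt, with_bold = FALSE)
    excl <- apply_task_exclusions(sub$trials)
    task_log[[sub$subject_id]] <- excl
    ema_summaries[[i]] <- summarize_ema(sub$ema)
    subjects[[sub$subject_id]] <- list(index = i, task_ok = excl$included)
  }
  ema_summaries <- dplyr::bind_rows(ema_summaries)
  ema_res <- apply_ema_exclusions(ema_summaries)
  task_excluded <- names(Filter(function(s) !s$task_ok, subjects))
  exclusion_log <- dplyr::bind_rows(
    ema_res$exclusion_log,
    tibble(subject_id = task_excluded,
           reason = vapply(task_excluded, function(id)
             paste(task_log[[id]]$reasons, collapse = "+"), character(1)))
  )
  included <- setdiff(ema_res$included$subject_id, task_excluded)
  if (length(included) < 4L) {
    abort(sprintf(
      "exclusion stage: only %d subject(s) retained; pipeline needs >= 4.",
      length(included)))
  }

  maps <- list()
  for (id in included) {
    i <- subjects[[id]]$index
    sub <- simulate_subject(sim, i, gt, with_bold = TRUE)
    maps[[id]] <- first_level_contrast(sub, cfg)$values
  }

  group <- group_stage(maps, sim, cfg)
  roi <- tryCatch(
    clusters_to_roi(group$clusters, mode = cfg$roi_mode),
    error = function(e) abort(paste("group stage:", conditionMessage(e)))
  )

  y <- ema_res$included$p_scf[match(sort(included),
                                    ema_res$included$subject_id)]
  X <- extract_features(maps, roi)
  decoding <- if (cfg$mode == "paper") {
    loso_predict(X, y, cfg$decoder)
  } else {
    honest_loso(maps, y, sim, cfg)
  }
  perm <- permutation_test(decoding, n_perm = cfg$n_perm,
                           seed = child_seed(sim$seed, "perm"))

  structure(
    list(
      n_simulated = sim$n_subjects, included = sort(included),
      exclusion_log = exclusion_log, ema_summaries = ema_summaries,
      group_stat = group$stat, smoothness = group$smooth,
      fwe = group$fwe, cluster_table = group$clusters, roi = roi,
      decoding = decoding, permutation = perm,
      roi_dice = dice_coefficient(roi, gt$roi_mask),
      true_p_fail = gt$true_p_fail,
      r_true_vs_obs = cor(gt$true_p_fail[match(sort(included),
                                               sprintf("sub-%02d",
                                                       seq_len(sim$n_subjects)))],
                          y),
      config = cfg, seed = sim$seed,
      package_version = as.character(utils::packageVersion("scdecode"))
    ),
    class = "run_report"
  )
}

# Second-level stage shared by the main pipeline and honest-mode folds.
group_stage <- function(maps, sim, cfg) {
  stat <- one_sample_t(maps)
  resid <- lapply(maps, function(m) m - Reduce(`+`, maps) / length(maps))
  smooth <- estimate_smoothness(resid, mask = stat$mask,
                                voxel_size_mm = sim$voxel_size_mm)
  fwe <- rft_voxel_fwe(stat, smooth, alpha = cfg$fwe_alpha)
  clusters <- extract_clusters(stat, voxel_size_mm = sim$voxel_size_mm,
                               cluster_p = cfg$cluster_p,
                               extent_mm3 = cfg$extent_mm3,
                               smooth = smooth, alpha = cfg$fwe_alpha)
  list(stat = stat, smooth = smooth, fwe = fwe, clusters = clusters)
}

# Honest-mode decoding: ROIs re-derived inside every outer fold.
honest_loso <- function(maps, y, sim, cfg) {
  ids <- sort(names(maps))
  n <- length(ids)
  y_pred <- rep(NA_real_, n)
  lambda_used <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train_ids <- ids[-i]
    g <- group_stage(maps[train_ids], sim, cfg)
    roi_i <- tryCatch(clusters_to_roi(g$clusters, mode = cfg$roi_mode),
                      error = function(e) NULL)
    if (is.null(roi_i)) {
      y_pred[i] <- mean(y[-i])
      next
    }
    Xi <- extract_features(maps[c(train_ids, ids[i])], roi_i)
    train_rows <- match(train_ids, rownames(Xi))
    test_row <- match(ids[i], rownames(Xi))
    lam <- select_lambda_nested(Xi[train_rows, , drop = FALSE], y[-i],
                                cfg$decoder)
    std <- standardizer(Xi[train_rows, , drop = FALSE],
                        cfg$decoder$standardize)
    fitp <- l1_path(std$apply(Xi[train_rows, , drop = FALSE]), y[-i],
                    cfg$decoder$lambda_grid)
    Xh <- std$apply(Xi[test_row, , drop = FALSE])
    if (fitp$padded) Xh <- cbind(Xh, 0)
    y_pred[i] <- drop(stats::predict(fitp$fit, Xh, s = lam,
                                     type = "response"))
    lambda_used[i] <- lam
  }
  structure(
    list(predictions = tibble(subject_id = ids, y_obs = y, y_pred = y_pred,
                              fold = seq_len(n), lambda = lambda_used),
         r = cor(y_pred, y), rmse = sqrt(mean((y_pred - y)^2)),
         chosen_lambda = lambda_used, coefficients = NULL,
         config = cfg$decoder),
    class = "decoding_result"
  )
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b Logical volumes on the same grid.
#' @return `2 |a & b| / (|a| + |b|)`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
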