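#' Simulate one subject's complete data
#'
#' Ratings, classified trials, EMA records, and (optionally) the BOLD run.
#' Every stage derives its own child seed from the master seed, the stage
#' name and the subject index, so stages are individually reproducible.
#'
#' @param cfg A [sim_config()].
#' @param subject Subject index.
#' @param gt Ground truth from [make_ground_truth()] (built if `NULL`).
#' @param with_bold Simulate the BOLD run (the expensive part)?
#' @return List with `subject_id`, `ratings`, `trials` (classified), `ema`,
#'   and when requested `bold`, `motion`, `n_scans`.
#' @export
simulate_subject <- function(cfg, subject, gt = NULL, with_bold = TRUE) {
  if (is.null(gt)) gt <- make_ground_truth(cfg)
  assert_count(subject, "subject")
  if (subject > cfg$n_subjects) {
    abort("`subject` exceeds `cfg$n_subjects`.")
  }
  sid <- sprintf("sub-%02d", subject)
  ratings <- simulate_ratings(cfg, child_seed(cfg$seed, "ratings", subject))
  trials <- simulate_decisions(ratings, gt$latent_self_control[subject], cfg,
                               child_seed(cfg$seed, "decisions", subject))
  trials <- classify_trials(trials, ratings)
  ema <- simulate_ema(gt$true_p_fail[subject], cfg,
                      child_seed(cfg$seed, "ema", subject))
  out <- list(subject_id = sid, ratings = ratings, trials = trials,
              ema = dplyr::mutate(ema, subject_id = sid, .before = 1))
  if (with_bold) {
    run <- simulate_bold(trials, gt, subject, cfg,
                         child_seed(cfg$seed, "bold", subject))
    out <- c(out, run)
  }
  out
}

#' Simulate and write a complete multi-subject dataset
#'
#' Writes a BIDS-like tree `sub-XX/{func,beh,ema}` with per-subject BOLD
#' NIfTI, events/ratings/EMA/motion TSVs, plus `ground_truth.json` at the
#' root. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param with_bold Write BOLD NIfTIs? (Tabular streams only when `FALSE`.)
#' @return Invisibly, a list with `ground_truth`, `subjects` (ids) and
#'   `root`.
#' @export
simulate_dataset <- function(cfg, out_dir, with_bold = TRUE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  gt <- make_ground_truth(cfg)
  ids <- character(cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    sub <- simulate_subject(cfg, i, gt, with_bold = with_bold)
    ids[i] <- sub$subject_id
    base <- file.path(out_dir, sub$subject_id)
    for (d in c("func", "beh", "ema")) {
      dir.create(file.path(base, d), recursive = TRUE, showWarnings = FALSE)
    }
    events <- dplyr::select(sub$trials, "trial_index", "item_id", "onset_s",
                            "duration_s", "decision", "missed",
                            "trial_class")
    readr::write_tsv(events, file.path(base, "func", "events.tsv"),
                     na = "n/a")
    readr::write_tsv(sub$ratings, file.path(base, "beh", "ratings.tsv"),
                     na = "n/a")
    readr::write_tsv(sub$ema, file.path(base, "ema", "ema.tsv"), na = "n/a")
    if (with_bold) {
      readr::write_tsv(sub$motion, file.path(base, "func", "motion.tsv"),
                       na = "n/a")
      img <- RNifti::asNifti(sub$bold,
                             pixdim = rep(cfg$voxel_size_mm, 3))
      RNifti::writeNifti(img, file.path(base, "func", "bold.nii.gz"))
    }
  }
  gt_json <- list(
    subjects = ids,
    latent_self_control = gt$latent_self_control,
    true_p_fail = gt$true_p_fail,
    pattern_expression = gt$pattern_expression,
    roi_voxels = gt$roi_voxels,
    grid_dims = cfg$grid_dims,
    beta_long_roi = gt$beta_long_roi
  )
  jsonlite::write_json(gt_json, file.path(out_dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(ground_truth = gt, subjects = ids, root = out_dir))
}
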