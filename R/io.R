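nifti_of <- function(vol, voxel_size_mm) {
  RNifti::asNifti(vol * 1, pixdim = rep(voxel_size_mm, 3))
}

#' Write a contrast map as NIfTI plus a JSON sidecar
#'
#' @param con A `contrast_map`.
#' @param path_prefix Output path without extension.
#' @param voxel_size_mm Isotropic voxel size.
#' @return Invisibly, the NIfTI path.
#' @export
write_contrast_map <- function(con, path_prefix, voxel_size_mm = 3) {
  if (is.null(dim(con$values)) || length(dim(con$values)) != 3L) {
    abort("Contrast map carries no volume geometry to write.")
  }
  vol <- con$values
  vol[is.na(vol)] <- 0
  RNifti::writeNifti(nifti_of(vol, voxel_size_mm),
                     paste0(path_prefix, ".nii.gz"))
  jsonlite::write_json(
    list(df_residual = con$df_residual,
         collapsed_note = con$collapsed_note,
         weights = as.list(con$weights[con$weights != 0])),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path_prefix, ".nii.gz"))
}

#' Write the group-analysis outputs
#'
#' Group t-map and ROI mask as NIfTI, cluster table as TSV (peak
#' coordinates in mm), thresholds as a JSON provenance sidecar.
#'
#' @param stat A `group_stat_map`.
#' @param table A `cluster_table`.
#' @param roi A `roi_mask` (optional).
#' @param dir Output directory.
#' @param voxel_size_mm Isotropic voxel size.
#' @return Invisibly, the directory.
#' @export
write_group_outputs <- function(stat, table, roi = NULL, dir,
                                voxel_size_mm = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tv <- stat$t_volume
  tv[!is.finite(tv)] <- 0
  RNifti::writeNifti(nifti_of(tv, voxel_size_mm),
                     file.path(dir, "group_tmap.nii.gz"))
  tab <- tidy(table)
  coord <- do.call(rbind, table$peak_coord_mm)
  tab$peak_x_mm <- coord[, 1]
  tab$peak_y_mm <- coord[, 2]
  tab$peak_z_mm <- coord[, 3]
  readr::write_tsv(tab, file.path(dir, "cluster_table.tsv"), na = "n/a")
  if (!is.null(roi)) {
    RNifti::writeNifti(nifti_of(array(as.logical(roi), dim(stat$t_volume)),
                                voxel_size_mm),
                       file.path(dir, "roi_mask.nii.gz"))
  }
  jsonlite::write_json(
    list(df = stat$df, n = stat$n,
         t_threshold = attr(table, "t_threshold"),
         roi_provenance = attr(roi, "provenance")),
    file.path(dir, "group_provenance.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}

#' Write decoding outputs
#'
#' Predictions TSV (subject, observed, predicted, fold, lambda), a result
#' JSON (r, RMSE, permutation p, configuration echo) and, when the
#' permutation result retained its null sample, a histogram-ready TSV of
#' null correlations.
#'
#' @param result A `decoding_result`.
#' @param perm A `permutation_result` (optional).
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_decoding_outputs <- function(result, perm = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$predictions, file.path(dir, "predictions.tsv"),
                   na = "n/a")
  cfg <- result$config
  jsonlite::write_json(
    list(r = result$r, rmse = result$rmse,
         n = nrow(result$predictions),
         chosen_lambda = result$chosen_lambda,
         permutation = if (!is.null(perm)) {
           list(p = perm$p, p_plus_one = perm$p_plus_one,
                n_perm = perm$n_perm, observed_r = perm$observed_r)
         },
         config = list(lambda_grid = cfg$lambda_grid,
                       cv_scheme = cfg$cv_scheme,
                       inner_criterion = cfg$inner_criterion,
                       standardize = cfg$standardize)),
    file.path(dir, "decoding_result.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(perm) && !is.null(perm$null_r)) {
    readr::write_tsv(tibble(null_r = perm$null_r),
                     file.path(dir, "null_distribution.tsv"))
  }
  invisible(dir)
}

#' Write a machine-readable pipeline report
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_run_report <- function(report, path) {
  g <- glance(report)
  jsonlite::write_json(
    list(summary = as.list(g),
         included = report$included,
         exclusions = report$exclusion_log,
         ema = report$ema_summaries,
         clusters = tidy(report$cluster_table),
         predictions = report$decoding$predictions,
         seed = report$seed,
         package_version = report$package_version,
         config = list(
           cluster_p = report$config$cluster_p,
           extent_mm3 = report$config$extent_mm3,
           fwe_alpha = report$config$fwe_alpha,
           hp_cutoff_s = report$config$hp_cutoff_s,
           n_perm = report$config$n_perm,
           mode = report$config$mode,
           sim = unclass(report$config$sim))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
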