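#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the cross-validated predictions of a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble with one row per subject: `subject_id`, `y_obs`,
#'   `y_pred`, `fold`, `lambda`.
#' @export
tidy.decoding_result <- function(x, ...) x$predictions

#' One-row summary of a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble with `r`, `rmse`, `n`, `median_lambda`.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(r = x$r, rmse = x$rmse, n = nrow(x$predictions),
         median_lambda = stats::median(x$predictions$lambda, na.rm = TRUE))
}

#' Tidy a cluster table (drops the voxel list-column)
#'
#' @param x A `cluster_table`.
#' @param ... Unused.
#' @return Plain tibble with per-cluster size, peak location and statistics.
#' @export
tidy.cluster_table <- function(x, ...) {
  out <- as_tibble(x)
  out$peak_coord_mm <- NULL
  out$voxels <- NULL
  out
}

#' One-row summary of a permutation test
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble with `observed_r`, `p`, `p_plus_one`, `n_perm`,
#'   `null_exceed_count`.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed_r = x$observed_r, p = x$p, p_plus_one = x$p_plus_one,
         n_perm = x$n_perm, null_exceed_count = x$null_exceed_count)
}

#' One-row summary of a pipeline run
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return Tibble with subject counts, cluster count, peak t, ROI Dice
#'   against ground truth, decoding r/RMSE and the permutation p.
#' @export
glance.run_report <- function(x, ...) {
  tibble(
    n_simulated = x$n_simulated, n_included = length(x$included),
    n_clusters = nrow(x$cluster_table),
    peak_t = if (nrow(x$cluster_table)) max(x$cluster_table$peak_t) else
      NA_real_,
    roi_dice = x$roi_dice, r = x$decoding$r, rmse = x$decoding$rmse,
    perm_p = x$permutation$p
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "Cross-validated decoding of %d subjects: r = %.3f, RMSE = %.3f\n",
    nrow(x$predictions), x$r, x$rmse))
  invisible(x)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d draws): observed r = %.3f, p %s\n",
              x$n_perm, x$observed_r,
              if (x$null_exceed_count == 0) x$p_label else
                sprintf("= %.5g", x$p)))
  invisible(x)
}

#' @export
print.run_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("Pipeline run (seed %d): %d/%d subjects retained, %d cluster(s),",
           " peak t = %.2f\n  ROI Dice vs truth = %.2f; decoding r = %.3f,",
           " RMSE = %.3f, permutation p = %.4g\n"),
    x$seed, g$n_included, g$n_simulated, g$n_clusters, g$peak_t, g$roi_dice,
    g$r, g$rmse, g$perm_p))
  invisible(x)
}
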