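#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline
#'   geom_histogram geom_vline geom_tile labs theme_minimal
#'   scale_fill_viridis_c coord_fixed
#' @export
ggplot2::autoplot

#' Scatter of cross-validated predictions against observed outcomes
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_result <- function(object, ...) {
  ggplot(object$predictions, aes(x = .data$y_obs, y = .data$y_pred)) +
    geom_point(alpha = 0.7) +
    geom_abline(linetype = 2, colour = "grey50") +
    labs(
      x = "Observed failure probability (EMA)",
      y = "Cross-validated prediction",
      title = sprintf("Decoding: r = %.3f, RMSE = %.3f", object$r,
                      object$rmse)
    ) +
    theme_minimal()
}

#' Null distribution of the permutation test
#'
#' Requires the test to have been run with `keep_null = TRUE`.
#'
#' @param object A `permutation_result`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permutation_result <- function(object, bins = 60, ...) {
  if (is.null(object$null_r)) {
    abort("Re-run `permutation_test()` with `keep_null = TRUE` to plot.")
  }
  ggplot(data.frame(r = object$null_r), aes(x = .data$r)) +
    geom_histogram(bins = bins, fill = "grey70") +
    geom_vline(xintercept = object$observed_r, colour = "black",
               linewidth = 1) +
    labs(x = "Null correlation", y = "Count",
         title = sprintf("Permutation null (%d draws), observed r = %.3f",
                         object$n_perm, object$observed_r)) +
    theme_minimal()
}

#' Axial slice of a group t-map
#'
#' @param stat A `group_stat_map`.
#' @param z Slice index (defaults to the slice containing the maximum t).
#' @param ... Unused.
#' @return A ggplot tile map.
#' @export
plot_stat_slice <- function(stat, z = NULL, ...) {
  tv <- stat$t_volume
  if (is.null(z)) {
    z <- arrayInd(which.max(replace(tv, !is.finite(tv), -Inf)), dim(tv))[3]
  }
  sl <- tv[, , z]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$t <- as.vector(sl)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$t)) +
    geom_tile() +
    scale_fill_viridis_c() +
    coord_fixed() +
    labs(title = sprintf("Group t-map, slice z = %d (df = %d)", z, stat$df),
         fill = "t") +
    theme_minimal()
}
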