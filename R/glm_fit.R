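#' Fit the first-level GLM at every voxel
#'
#' Ordinary least squares of each voxel's time series on the design matrix.
#' An optional AR(1) Cochrane-Orcutt mode estimates the pooled lag-1
#' residual autocorrelation, quasi-differences data and design, and refits.
#'
#' @param bold 4-D array (`x, y, z, scan`) or an `n_scans x n_voxels`
#'   matrix.
#' @param design A [build_design_matrix()] object.
#' @param mask Optional logical volume restricting the fit.
#' @param prewhiten `"none"` (default) or `"ar1"`.
#' @return An object of class `glm_fit`: `betas` (`n_columns x n_voxels`),
#'   `sigma2`, `df_residual`, `xtx_inv`, `column_labels`, `task_columns`,
#'   `mask`, `dims`, `residuals`.
#' @export
fit_glm <- function(bold, design, mask = NULL, prewhiten = c("none", "ar1")) {
  prewhiten <- match.arg(prewhiten)
  X <- design$values
  dims <- NULL
  if (is.array(bold) && length(dim(bold)) == 4L) {
    dims <- dim(bold)[1:3]
    Y <- t(matrix(bold, nrow = prod(dims), ncol = dim(bold)[4]))
  } else {
    Y <- as.matrix(bold)
  }
  if (nrow(Y) != nrow(X)) abort("Scan count of data and design disagree.")
  if (anyNA(Y)) abort("BOLD data contain NaN/NA values.")
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    Y <- Y[, keep, drop = FALSE]
  } else {
    keep <- rep(TRUE, ncol(Y))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- design$column_labels[setdiff(seq_len(ncol(X)),
                                        qx$pivot[seq_len(qx$rank)])]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (prewhiten == "ar1") {
    res0 <- Y - X %*% qr.coef(qx, Y)
    n <- nrow(res0)
    denom <- sum(res0[-n, ]^2)
    rho <- if (denom > 0) sum(res0[-1, ] * res0[-n, ]) / denom else 0
    X <- X[-1, , drop = FALSE] - rho * X[-n, , drop = FALSE]
    Y <- Y[-1, , drop = FALSE] - rho * Y[-n, , drop = FALSE]
    qx <- qr(X)
  }
  betas <- qr.coef(qx, Y)
  resid <- Y - X %*% betas
  df <- nrow(X) - qx$rank
  sigma2 <- colSums(resid^2) / df
  structure(
    list(betas = betas, sigma2 = sigma2, df_residual = df,
         xtx_inv = chol2inv(chol(crossprod(X))),
         column_labels = design$column_labels,
         task_columns = design$task_columns, mask = keep, dims = dims,
         residuals = resid, design = design),
    class = "glm_fit"
  )
}

#' Compute the long > short contrast map for one fitted subject
#'
#' Averages the condition estimates within the collapsed long-term set and
#' within the collapsed short-term set, then subtracts. When one member of
#' a pair was dropped (no trials), the surviving member carries weight 1;
#' this is recorded. Errors when either side is entirely empty.
#'
#' @param fit A [fit_glm()] object.
#' @param long_labels,short_labels Condition labels forming each side.
#' @return An object of class `contrast_map`: `values` (vector over fitted
#'   voxels, or 3-D volume when `fit` carries dims), `se`, `t`,
#'   `df_residual`, `weights`, `collapsed_note`.
#' @export
compute_contrast <- function(fit,
                             long_labels = c("LT_A", "LT_B"),
                             short_labels = c("ST_A", "ST_B")) {
  present <- fit$column_labels
  long_in <- intersect(long_labels, present)
  short_in <- intersect(short_labels, present)
  if (!length(long_in) || !length(short_in)) {
    abort("Contrast undefined: an entire collapsed side has no regressor.")
  }
  w <- stats::setNames(numeric(length(present)), present)
  w[long_in] <- 1 / length(long_in)
  w[short_in] <- -1 / length(short_in)
  est <- drop(crossprod(w, fit$betas))
  var_scale <- drop(t(w) %*% fit$xtx_inv %*% w)
  se <- sqrt(var_scale * fit$sigma2)
  note <- c(
    if (length(long_in) < length(long_labels)) "long_side_single_regressor",
    if (length(short_in) < length(short_labels)) "short_side_single_regressor"
  )
  vol <- est
  if (!is.null(fit$dims)) {
    vol <- array(NA_real_, fit$dims)
    vol[fit$mask] <- est
  }
  structure(
    list(values = vol, estimate = est, se = se, t = est / se,
         df_residual = fit$df_residual, weights = w,
         collapsed_note = note %||% character()),
    class = "contrast_map"
  )
}
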