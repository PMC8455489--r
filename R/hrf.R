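#' Canonical haemodynamic response parameters
#'
#' The canonical double-gamma HRF: a positive gamma density peaking around
#' 5 s minus a scaled gamma density modelling the post-stimulus undershoot.
#' Defaults are the conventional values (peak delay 6 s, undershoot delay
#' 16 s, unit dispersions, undershoot ratio 1/6, 32-s support, 16 microtime
#' bins per scan for event sampling).
#'
#' @param peak_delay_s,undershoot_delay_s Gamma delays (shape x scale) in s.
#' @param peak_disp,undershoot_disp Gamma dispersions (scale parameters).
#' @param undershoot_ratio Weight of the undershoot component.
#' @param length_s Kernel support in seconds.
#' @param microtime_bins Bins per TR used when building regressors.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       undershoot_ratio = 1 / 6, length_s = 32,
                       microtime_bins = 16L) {
  vals <- c(peak_delay_s, undershoot_delay_s, peak_disp, undershoot_disp,
            length_s, microtime_bins)
  if (any(vals <= 0) || undershoot_ratio < 0) {
    abort("HRF parameters must be positive (undershoot_ratio >= 0).")
  }
  if (length_s < undershoot_delay_s) {
    abort("`length_s` must cover the undershoot component.")
  }
  structure(as.list(environment()), class = "hrf_params")
}

#' Sample the canonical double-gamma HRF
#'
#' Evaluates the difference of two gamma densities on a regular grid over
#' `[0, length_s]` and scales the kernel to unit peak.
#'
#' @param p An [hrf_params()] object.
#' @param dt_s Sampling interval in seconds (> 0).
#' @return Numeric vector of kernel values at `seq(0, length_s, by = dt_s)`.
#' @export
canonical_hrf <- function(p = hrf_params(), dt_s) {
  if (dt_s <= 0) abort("`dt_s` must be positive.")
  t <- seq(0, p$length_s, by = dt_s)
  h <- dgamma(t, shape = p$peak_delay_s / p$peak_disp, scale = p$peak_disp) -
    p$undershoot_ratio *
      dgamma(t, shape = p$undershoot_delay_s / p$undershoot_disp,
             scale = p$undershoot_disp)
  h / max(h)
}

# Discrete-cosine drift basis: columns k = 1..K with period 2T/k; K =
# floor(2T / cutoff), so retained periods are at or above the cutoff.
dct_drift_basis <- function(n_scans, tr_s, hp_cutoff_s) {
  total_t <- n_scans * tr_s
  if (!is.finite(hp_cutoff_s)) {
    return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  }
  k_max <- floor(2 * total_t / hp_cutoff_s)
  if (k_max < 1L) return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  i <- seq_len(n_scans) - 1
  basis <- vapply(seq_len(k_max), function(k) {
    sqrt(2 / n_scans) * cos(pi * (2 * i + 1) * k / (2 * n_scans))
  }, numeric(n_scans))
  colnames(basis) <- paste0("drift_", seq_len(k_max))
  basis
}

#' Build a first-level design matrix
#'
#' One boxcar regressor per nonempty trial class, built at microtime
#' resolution (TR / `microtime_bins`), convolved with the canonical HRF and
#' sampled at the scan frame times; discrete-cosine drift columns for
#' periods above the high-pass cutoff; motion nuisance series and a
#' constant appended. Empty conditions are dropped and recorded.
#'
#' @param events Tibble with columns `onset_s`, `duration_s`, `condition`.
#' @param motion Matrix or tibble of nuisance series (`n_scans` rows), or
#'   `NULL`.
#' @param n_scans Number of scans.
#' @param tr_s Repetition time (s).
#' @param hrf An [hrf_params()] object.
#' @param hp_cutoff_s High-pass cutoff period in seconds (default 128;
#'   `Inf` disables drift columns).
#' @return An object of class `design_matrix`: list with `values`
#'   (`n_scans x n_columns`), `column_labels`, `task_columns`,
#'   `frame_times_s`, `dropped_conditions`.
#' @export
build_design_matrix <- function(events, motion = NULL, n_scans, tr_s,
                                hrf = hrf_params(), hp_cutoff_s = 128) {
  total_t <- n_scans * tr_s
  if (any(events$onset_s < 0) || any(events$onset_s >= total_t)) {
    abort("Event onsets must lie within the scan duration.")
  }
  if (anyDuplicated(events$onset_s)) {
    abort("Overlapping events at identical onsets.")
  }
  dt <- tr_s / hrf$microtime_bins
  n_fine <- ceiling(total_t / dt)
  kernel <- canonical_hrf(hrf, dt)
  frame_idx <- round((seq_len(n_scans) - 1) * tr_s / dt) + 1L

  conds <- unique(as.character(events$condition))
  task <- sapply(conds, function(cn) {
    ev <- events[as.character(events$condition) == cn, ]
    box <- numeric(n_fine)
    for (r in seq_len(nrow(ev))) {
      from <- floor(ev$onset_s[r] / dt) + 1L
      to <- min(n_fine, ceiling((ev$onset_s[r] + max(ev$duration_s[r], dt)) / dt))
      box[from:to] <- 1
    }
    conv <- convolve(box, rev(kernel), type = "open")[seq_len(n_fine)]
    conv[frame_idx]
  })
  task <- matrix(task, nrow = n_scans, dimnames = list(NULL, conds))
  dropped <- conds[colSums(abs(task)) == 0]
  task <- task[, setdiff(conds, dropped), drop = FALSE]

  drift <- dct_drift_basis(n_scans, tr_s, hp_cutoff_s)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans) abort("`motion` must have `n_scans` rows.")
    colnames(motion) <- paste0("motion_", seq_len(ncol(motion)))
  } else {
    motion <- matrix(numeric(0), nrow = n_scans, ncol = 0)
  }
  const <- matrix(1, n_scans, 1, dimnames = list(NULL, "constant"))
  values <- cbind(task, motion, const, drift)
  structure(
    list(values = values, column_labels = colnames(values),
         task_columns = colnames(task),
         frame_times_s = (seq_len(n_scans) - 1) * tr_s,
         dropped_conditions = dropped, tr_s = tr_s,
         hp_cutoff_s = hp_cutoff_s),
    class = "design_matrix"
  )
}
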