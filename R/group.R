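#' Second-level one-sample t-field on contrast maps
#'
#' The long-minus-short contrast images are within-subject differences, so
#' the one-sample t on them is the paired t-test between the collapsed
#' conditions. Zero-variance voxels get signed infinite t and are flagged.
#'
#' @param contrast_maps List of `contrast_map` objects or 3-D arrays, or an
#'   `n_subjects x n_voxels` matrix.
#' @param mask Optional logical volume.
#' @param dims Grid dims when a matrix is supplied.
#' @return Object of class `group_stat_map`: `t_volume`, `mean_volume`,
#'   `df` (N-1), `n`, `mask`, `dims`, `zero_variance` (indices).
#' @export
one_sample_t <- function(contrast_maps, mask = NULL, dims = NULL) {
  if (is.list(contrast_maps)) {
    vols <- lapply(contrast_maps, function(m) {
      if (inherits(m, "contrast_map")) m$values else m
    })
    dims <- dim(vols[[1]])
    M <- do.call(rbind, lapply(vols, as.vector))
  } else {
    M <- as.matrix(contrast_maps)
  }
  n <- nrow(M)
  if (n < 3L) abort("Need at least 3 contrast maps.")
  if (is.null(mask)) mask <- array(TRUE, dim = dims %||% c(ncol(M), 1, 1))
  keep <- as.vector(mask)
  mu <- colMeans(M)
  s <- apply(M, 2, sd)
  tval <- rep(NA_real_, ncol(M))
  zero_var <- which(keep & s == 0)
  ok <- keep & s > 0
  tval[ok] <- mu[ok] / (s[ok] / sqrt(n))
  tval[zero_var] <- sign(mu[zero_var]) * Inf  # zero mean, zero sd -> t = 0
  tval[zero_var][mu[zero_var] == 0] <- 0
  dims <- dims %||% c(ncol(M), 1L, 1L)
  structure(
    list(t_volume = array(tval, dims), mean_volume = array(mu, dims),
         df = n - 1L, n = n, mask = array(keep, dims), dims = dims,
         zero_variance = zero_var),
    class = "group_stat_map"
  )
}

#' Estimate field smoothness from residual maps
#'
#' Kiebel/Worsley estimator: residual maps are normalised voxelwise to unit
#' sum of squares across maps, the variance of their spatial derivatives
#' per axis gives the roughness, and FWHM per axis is
#' `sqrt(4 log 2 / roughness)` (in voxels, scaled to mm). Resolution-element
#' (resel) counts for the mask follow from lattice counting of in-mask
#' vertices, edges, faces and cubes.
#'
#' @param residual_maps List of 3-D arrays or an `n_maps x n_voxels` matrix.
#' @param mask Logical volume.
#' @param voxel_size_mm Isotropic voxel size.
#' @param dims Grid dims when a matrix is supplied.
#' @return Object of class `smoothness_estimate`: `fwhm_mm`, `fwhm_vox`,
#'   `resels` (R0..R3), `n_mask_voxels`.
#' @export
estimate_smoothness <- function(residual_maps, mask, voxel_size_mm,
                                dims = NULL) {
  if (is.list(residual_maps)) {
    dims <- dim(residual_maps[[1]])
    R <- do.call(rbind, lapply(residual_maps, as.vector))
  } else {
    R <- as.matrix(residual_maps)
  }
  if (nrow(R) < 2L) abort("Need at least 2 residual maps.")
  dims <- dims %||% dim(mask)
  ss <- sqrt(colSums(R^2))
  ss[ss == 0] <- NA_real_
  U <- sweep(R, 2, ss, "/")
  m <- array(as.vector(mask), dims)
  lam <- numeric(3)
  for (ax in 1:3) {
    n_ax <- dims[ax]
    idx_lo <- slice_index(dims, ax, seq_len(n_ax - 1L))
    idx_hi <- slice_index(dims, ax, seq(2L, n_ax))
    pair_ok <- m[idx_lo] & m[idx_hi]
    d <- U[, idx_hi[pair_ok], drop = FALSE] - U[, idx_lo[pair_ok], drop = FALSE]
    lam[ax] <- mean(colSums(d^2), na.rm = TRUE)
  }
  fwhm_vox <- sqrt(4 * log(2) / lam)
  structure(
    list(fwhm_vox = fwhm_vox, fwhm_mm = fwhm_vox * voxel_size_mm,
         resels = resel_counts(m, fwhm_vox), n_mask_voxels = sum(m)),
    class = "smoothness_estimate"
  )
}

# Linear indices of a full slab along `axis` at positions `at`.
slice_index <- function(dims, axis, at) {
  coords <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  coords[[axis]] <- at
  g <- as.matrix(expand.grid(coords))
  as.vector(g[, 1] + (g[, 2] - 1) * dims[1] +
              (g[, 3] - 1) * dims[1] * dims[2])
}

# Worsley lattice resel counts R0..R3 for a mask at given FWHM (voxels).
resel_counts <- function(mask, fwhm_vox) {
  d <- dim(mask)
  m <- mask
  cnt_edge <- function(ax) {
    lo <- slice_index(d, ax, seq_len(d[ax] - 1L))
    hi <- slice_index(d, ax, seq(2L, d[ax]))
    sum(m[lo] & m[hi])
  }
  shift_and <- function(axes) {
    keep <- array(TRUE, d - ifelse(seq_len(3) %in% axes, 1L, 0L))
    sub <- function(offsets) {
      i <- seq_len(d[1] - (1 %in% axes)) + offsets[1]
      j <- seq_len(d[2] - (2 %in% axes)) + offsets[2]
      k <- seq_len(d[3] - (3 %in% axes)) + offsets[3]
      m[i, j, k, drop = FALSE]
    }
    offs <- expand.grid(x = if (1 %in% axes) 0:1 else 0,
                        y = if (2 %in% axes) 0:1 else 0,
                        z = if (3 %in% axes) 0:1 else 0)
    for (r in seq_len(nrow(offs))) keep <- keep & sub(as.integer(offs[r, ]))
    sum(keep)
  }
  P <- sum(m)
  Ex <- cnt_edge(1); Ey <- cnt_edge(2); Ez <- cnt_edge(3)
  Fxy <- shift_and(c(1, 2)); Fxz <- shift_and(c(1, 3)); Fyz <- shift_and(c(2, 3))
  C <- shift_and(1:3)
  r <- 1 / fwhm_vox
  c(R0 = P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C,
    R1 = (Ex - Fxy - Fxz + C) * r[1] + (Ey - Fxy - Fyz + C) * r[2] +
      (Ez - Fxz - Fyz + C) * r[3],
    R2 = (Fxy - C) * r[1] * r[2] + (Fxz - C) * r[1] * r[3] +
      (Fyz - C) * r[2] * r[3],
    R3 = C * r[1] * r[2] * r[3])
}

# Euler-characteristic densities of a t-field with `df` degrees of freedom
# (Worsley closed forms; dimension d = 0..3).
ec_density_t <- function(t, df, d) {
  a <- 4 * log(2)
  cc <- (1 + t^2 / df)^((1 - df) / 2)
  switch(as.character(d),
    "0" = pt(t, df, lower.tail = FALSE),
    "1" = sqrt(a) / (2 * pi) * cc,
    "2" = a / (2 * pi)^1.5 * cc * t *
      exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2),
    "3" = a^1.5 / (2 * pi)^2 * cc * ((df - 1) * t^2 / df - 1)
  )
}

#' Voxel-level family-wise error correction by random field theory
#'
#' The FWE-corrected p-value of a peak height `t` is the expected Euler
#' characteristic of the excursion set,
#' `p_FWE(t) = min(1, sum_d R_d rho_d(t))`, with resel counts `R_d` from
#' the smoothness estimate and t-field EC densities `rho_d`. The critical
#' threshold solves `p_FWE(t) = alpha` by monotone root-finding.
#'
#' @param stat A [one_sample_t()] object.
#' @param smooth A [estimate_smoothness()] object.
#' @param alpha Family-wise error level in (0, 1).
#' @return List with `p_fwe_volume`, `t_fwe` (critical threshold), `alpha`,
#'   and the function `p_fwe(t)`.
#' @export
rft_voxel_fwe <- function(stat, smooth, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  R <- smooth$resels
  df <- stat$df
  p_fun <- function(t) {
    pmin(1, pmax(0,
      R[1] * ec_density_t(t, df, 0) + R[2] * ec_density_t(t, df, 1) +
        R[3] * ec_density_t(t, df, 2) + R[4] * ec_density_t(t, df, 3)))
  }
  # the EC sum is only monotone beyond its mode; root-find from there
  grid <- seq(0.25, 10, by = 0.05)
  vals <- p_fun(grid)
  lo <- grid[which.max(vals)]
  hi <- 10
  while (p_fun(hi) > alpha && hi < 1e4) hi <- hi * 2
  t_fwe <- if (p_fun(lo) <= alpha) lo else
    stats::uniroot(function(t) p_fun(t) - alpha, c(lo, hi), tol = 1e-8)$root
  pv <- array(NA_real_, stat$dims)
  inside <- which(stat$mask & is.finite(stat$t_volume))
  pv[inside] <- p_fun(stat$t_volume[inside])
  pv[stat$mask & stat$t_volume == Inf] <- 0
  list(p_fwe_volume = pv, t_fwe = t_fwe, alpha = alpha, p_fwe = p_fun)
}

# Neighbour offsets for 6/18/26-connectivity.
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1,
                 abort("`connectivity` must be 6, 18 or 26."))
  g[keep, , drop = FALSE]
}

#' Extract suprathreshold clusters with an extent rule
#'
#' Voxels with uncorrected p below `cluster_p` (t above the corresponding
#' quantile) form connected components (18-connectivity by default, the
#' SPM convention); components smaller than `extent_mm3` are discarded.
#' Clusters are ordered by peak t (ties by lexicographic peak coordinate),
#' and each peak gets its RFE-corrected voxel p-value when a smoothness
#' estimate is supplied.
#'
#' @param stat A [one_sample_t()] object.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param cluster_p Cluster-forming (uncorrected, one-sided) p threshold.
#' @param extent_mm3 Minimum cluster volume in mm^3.
#' @param smooth Optional [estimate_smoothness()] for peak FWE p-values.
#' @param alpha FWE level used for the `survives_fwe` flag.
#' @param connectivity 6, 18 or 26.
#' @return A tibble of class `cluster_table`: `cluster_id`, `n_voxels`,
#'   `size_mm3`, `peak_x/y/z` (voxel indices), `peak_coord_mm`, `peak_t`,
#'   `peak_p_fwe`, `survives_fwe`, and a `voxels` list-column of linear
#'   indices. Attributes `dims`, `t_threshold`.
#' @export
extract_clusters <- function(stat, voxel_size_mm, cluster_p = 0.001,
                             extent_mm3 = 270, smooth = NULL, alpha = 0.05,
                             connectivity = 18) {
  if (cluster_p <= 0 || cluster_p >= 1) abort("`cluster_p` must be in (0,1).")
  t_thr <- qt(cluster_p, stat$df, lower.tail = FALSE)
  dims <- stat$dims
  supra <- array(stat$mask & !is.na(stat$t_volume) &
                   stat$t_volume > t_thr, dims)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, dims)
  comp <- 0L
  todo <- which(supra)
  for (start in todo) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      ci <- arrayInd(v, dims)
      nb <- sweep(offs, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      new <- lin[supra[lin] & labels[lin] == 0L]
      labels[new] <- comp
      queue <- c(queue, new)
    }
  }
  vox_per_mm3 <- voxel_size_mm^3
  rows <- list()
  for (k in seq_len(comp)) {
    vox <- which(labels == k)
    size_mm3 <- length(vox) * vox_per_mm3
    if (size_mm3 < extent_mm3) next
    tv <- stat$t_volume[vox]
    peak_candidates <- vox[tv == max(tv)]
    peak <- peak_candidates[order(peak_candidates)][1]
    pc <- arrayInd(peak, dims)
    rows[[length(rows) + 1L]] <- tibble(
      n_voxels = length(vox), size_mm3 = size_mm3,
      peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
      peak_t = max(tv), voxels = list(vox)
    )
  }
  tab <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(n_voxels = integer(), size_mm3 = numeric(), peak_x = integer(),
           peak_y = integer(), peak_z = integer(), peak_t = numeric(),
           voxels = list())
  tab <- tab[order(-tab$peak_t, tab$peak_x, tab$peak_y, tab$peak_z), ]
  tab$cluster_id <- seq_len(nrow(tab))
  if (!is.null(smooth)) {
    fwe <- rft_voxel_fwe(stat, smooth, alpha)
    tab$peak_p_fwe <- fwe$p_fwe(tab$peak_t)
    tab$survives_fwe <- tab$peak_p_fwe < alpha
  } else {
    tab$peak_p_fwe <- NA_real_
    tab$survives_fwe <- NA
  }
  tab$peak_coord_mm <- purrr::pmap(
    list(tab$peak_x, tab$peak_y, tab$peak_z),
    function(x, y, z) (c(x, y, z) - 1) * voxel_size_mm)
  out <- dplyr::relocate(tab, "cluster_id")
  attr(out, "dims") <- dims
  attr(out, "t_threshold") <- t_thr
  class(out) <- c("cluster_table", class(out))
  out
}

#' Build the decoding ROI mask from retained clusters
#'
#' @param table A [extract_clusters()] table.
#' @param mode `"all_clusters"` (default; every retained cluster, matching
#'   the use of whole clusters as ROIs) or `"fwe_peaks_only"` (only
#'   clusters whose peak survives voxel-level FWE).
#' @return Logical volume of class `roi_mask` with attributes `provenance`
#'   and `cluster_id` (integer volume labelling each ROI voxel by cluster).
#' @export
clusters_to_roi <- function(table, mode = c("all_clusters",
                                            "fwe_peaks_only")) {
  mode <- match.arg(mode)
  keep <- if (mode == "fwe_peaks_only") {
    which(isTRUE_v(table$survives_fwe))
  } else {
    seq_len(nrow(table))
  }
  if (!length(keep)) abort("no ROI available: no retained cluster.")
  dims <- attr(table, "dims")
  mask <- array(FALSE, dims)
  ids <- array(0L, dims)
  for (k in keep) {
    vox <- table$voxels[[k]]
    mask[vox] <- TRUE
    ids[vox] <- table$cluster_id[k]
  }
  structure(mask, cluster_id = ids,
            provenance = list(mode = mode,
                              t_threshold = attr(table, "t_threshold"),
                              clusters = table$cluster_id[keep]),
            class = c("roi_mask", "array"))
}
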