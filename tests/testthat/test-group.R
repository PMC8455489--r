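stat_from_volume <- function(tv, df = 20, mask = NULL) {
  # build a group_stat_map around a hand-constructed t-volume
  structure(list(t_volume = tv, mean_volume = tv, df = df, n = df + 1,
                 mask = mask %||% array(TRUE, dim(tv)), dims = dim(tv),
                 zero_variance = integer()),
            class = "group_stat_map")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("one-sample t matches the hand formula and the t.test oracle", {
  vals <- c(1, 2, 3, 4)
  set.seed(2)
  M <- matrix(rnorm(4 * 50), 4)
  M[, 1] <- vals
  st <- one_sample_t(M, dims = c(50, 1, 1))
  expect_equal(st$t_volume[1], 2.5 / (sd(vals) / 2), tolerance = 1e-12)
  expect_equal(st$t_volume[1], hand_t(vals), tolerance = 1e-12)
  for (v in c(5, 17)) {
    expect_equal(st$t_volume[v], unname(t.test(M[, v])$statistic),
                 tolerance = 1e-10)
  }
  expect_equal(st$df, 3)
})

test_that("identical zero maps give zero t and flagged zero variance", {
  M <- matrix(0, 5, 10)
  st <- one_sample_t(M, dims = c(10, 1, 1))
  expect_true(all(st$t_volume == 0))
  expect_length(st$zero_variance, 10)
  # constant nonzero maps: signed infinity
  st2 <- one_sample_t(matrix(2, 5, 4), dims = c(4, 1, 1))
  expect_true(all(st2$t_volume == Inf))
})

test_that("smoothness estimator reaches its known white-noise limit", {
  set.seed(31)
  dims <- c(22, 22, 22)
  R <- matrix(rnorm(20 * prod(dims)), 20)
  est <- estimate_smoothness(R, array(TRUE, dims), voxel_size_mm = 3,
                             dims = dims)
  # discrete white-noise limit: derivative variance 2 -> FWHM sqrt(2 log 2)
  expect_equal(mean(est$fwhm_vox), sqrt(2 * log(2)), tolerance = 0.05)
  # units: doubling voxel size doubles FWHM in mm
  est6 <- estimate_smoothness(R, array(TRUE, dims), voxel_size_mm = 6,
                              dims = dims)
  expect_equal(est6$fwhm_mm, 2 * est$fwhm_mm)
})

test_that("smoothness estimator recovers an applied 8-mm kernel", {
  set.seed(32)
  dims <- c(22, 22, 22)
  R <- matrix(rnorm(16 * prod(dims)), 16)
  Rs <- t(smooth_volume(t(R), fwhm_mm = 8, voxel_mm = 3, dims = dims))
  est <- estimate_smoothness(Rs, array(TRUE, dims), voxel_size_mm = 3,
                             dims = dims)
  expect_true(all(abs(est$fwhm_mm - 8) / 8 < 0.15))
})

test_that("resel counts reproduce the cuboid closed form", {
  mask <- array(TRUE, c(10, 10, 10))
  f <- c(2, 2, 2)
  R <- scdecode:::resel_counts(mask, f)
  expect_equal(unname(R["R3"]), 9^3 / 8)
  expect_equal(unname(R["R0"]), 1)
  expect_equal(unname(R["R2"]), 3 * 9^2 / 4)
  expect_equal(unname(R["R1"]), 3 * 9 / 2)
})

test_that("RFT correction reduces to the single-test limit", {
  tv <- array(2, c(2, 2, 2))
  st <- stat_from_volume(tv, df = 15)
  sm <- structure(list(fwhm_vox = c(2, 2, 2), fwhm_mm = c(6, 6, 6),
                       resels = c(R0 = 1, R1 = 0, R2 = 0, R3 = 0),
                       n_mask_voxels = 8), class = "smoothness_estimate")
  fwe <- rft_voxel_fwe(st, sm, alpha = 0.05)
  expect_equal(fwe$p_fwe(2.5), pt(2.5, 15, lower.tail = FALSE))
  expect_equal(fwe$t_fwe, qt(0.95, 15), tolerance = 1e-6)
  expect_error(rft_voxel_fwe(st, sm, alpha = 1.2), "alpha")
})

test_that("FWE threshold drops with smoothness and respects bounds", {
  mask <- array(TRUE, c(16, 16, 16))
  st <- stat_from_volume(array(1, c(16, 16, 16)), df = 29)
  thr <- vapply(c(1.5, 2, 3, 4), function(f) {
    sm <- structure(list(fwhm_vox = rep(f, 3), fwhm_mm = rep(3 * f, 3),
                         resels = scdecode:::resel_counts(mask, rep(f, 3)),
                         n_mask_voxels = sum(mask)),
                    class = "smoothness_estimate")
    rft_voxel_fwe(st, sm, 0.05)$t_fwe
  }, numeric(1))
  expect_true(all(diff(thr) < 0))
  # corrected threshold between uncorrected and Bonferroni
  expect_true(all(thr >= qt(0.95, 29)))
  expect_lt(thr[4], qt(1 - 0.05 / sum(mask), 29))
})

test_that("cluster extraction applies the 270 mm^3 extent rule", {
  # at 3-mm voxels the threshold is 270/27 = 10 voxels
  dims <- c(14, 14, 14)
  tv <- array(0, dims)
  # blob A: 3x2x2 = 12 voxels (retained, 324 mm^3)
  tv[2:4, 2:3, 2:3] <- 5
  tv[3, 2, 2] <- 6  # peak
  # blob B: 3x3x1 = 9 voxels (dropped)
  tv[9:11, 9:11, 9] <- 7
  # isolated single voxel (dropped)
  tv[13, 2, 13] <- 8
  st <- stat_from_volume(tv, df = 20)
  tab <- extract_clusters(st, voxel_size_mm = 3, cluster_p = 0.001,
                          extent_mm3 = 270)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_voxels, 12)
  expect_equal(tab$size_mm3, 324)
  expect_equal(tab$peak_t, 6)
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z), c(3, 2, 2))
})

test_that("cluster components agree with an igraph oracle", {
  set.seed(5)
  dims <- c(12, 12, 12)
  tv <- array(0, dims)
  supra <- sample(prod(dims), 180)
  tv[supra] <- runif(180, 4, 9)
  st <- stat_from_volume(tv, df = 25)
  tab <- extract_clusters(st, voxel_size_mm = 3, cluster_p = 0.001,
                          extent_mm3 = 0, connectivity = 18)
  oracle <- igraph_components(which(tv > qt(0.999, 25)), dims, 18)
  expect_equal(nrow(tab), length(oracle))
  got_sets <- lapply(tab$voxels, sort)
  want_sets <- lapply(oracle, function(v) sort(unname(v)))
  for (s in want_sets) {
    expect_true(any(vapply(got_sets, identical, logical(1), y = s)))
  }
})

test_that("cluster ordering is canonical and ROI modes behave", {
  dims <- c(14, 14, 14)
  tv <- array(0, dims)
  tv[2:4, 2:4, 2:4] <- 4.2   # 27 voxels, modest peak
  tv[8:11, 8:10, 8:10] <- 5  # 36 voxels, higher peak
  st <- stat_from_volume(tv, df = 40)
  sm <- structure(list(fwhm_vox = c(2, 2, 2), fwhm_mm = c(6, 6, 6),
                       resels = scdecode:::resel_counts(array(TRUE, dims),
                                                        c(2, 2, 2)),
                       n_mask_voxels = prod(dims)),
                  class = "smoothness_estimate")
  tab <- extract_clusters(st, 3, smooth = sm)
  expect_equal(tab$peak_t, sort(tab$peak_t, decreasing = TRUE))
  expect_equal(tab$cluster_id, seq_len(nrow(tab)))

  roi <- clusters_to_roi(tab)
  expect_equal(sum(roi), 27 + 36)
  ids <- attr(roi, "cluster_id")
  expect_equal(sum(ids == 1), 36)  # highest-peak cluster is id 1

  # a 15-voxel cluster maps to a 15-voxel ROI
  tv2 <- array(0, dims); tv2[3:7, 3:5, 3] <- 6
  tab2 <- extract_clusters(stat_from_volume(tv2, df = 40), 3)
  expect_equal(sum(clusters_to_roi(tab2)), 15)

  empty <- extract_clusters(stat_from_volume(array(0, dims), df = 40), 3)
  expect_error(clusters_to_roi(empty), "no ROI available")
  # fwe mode with no surviving peak also halts
  tab$survives_fwe <- FALSE
  expect_error(clusters_to_roi(tab, mode = "fwe_peaks_only"),
               "no ROI available")
})

test_that("planted multi-blob fields recover the planted configuration", {
  set.seed(77)
  dims <- c(16, 16, 16)
  centers <- list(c(4, 5, 10), c(12, 5, 10), c(8, 12, 7))
  tv <- array(rnorm(prod(dims), sd = 0.5), dims)
  truth <- array(FALSE, dims)
  for (ctr in centers) {
    idx <- as.matrix(expand.grid(1:16, 1:16, 1:16))
    d <- sqrt(colSums((t(idx) - ctr)^2))
    blob <- d <= 2
    truth[idx[blob, ]] <- TRUE
    tv[idx[blob, ]] <- tv[idx[blob, ]] + 8
  }
  st <- stat_from_volume(tv, df = 30)
  tab <- extract_clusters(st, 3)
  expect_equal(nrow(tab), 3)
  roi <- clusters_to_roi(tab)
  expect_gt(dice_coefficient(roi, truth), 0.9)
})
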