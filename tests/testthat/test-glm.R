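test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(hrf_params(), dt_s = 0.01)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # gamma(shape 6, scale 1) modes at t = 5; the tiny undershoot mass there
  # shifts the peak by less than the grid step
  t_grid <- seq(0, 32, by = 0.01)
  expect_lt(abs(t_grid[which.max(h)] - 5.0), 0.05)
  # without an undershoot the kernel is a scaled gamma density: nonnegative
  h0 <- canonical_hrf(hrf_params(undershoot_ratio = 0), dt_s = 0.1)
  expect_true(all(h0 >= 0))
  # with the default undershoot it dips below zero after the peak
  expect_lt(min(h), 0)
})

test_that("drift basis column count follows the period condition", {
  for (case in list(c(200, 2, 128), c(100, 2, 128), c(300, 2.5, 100))) {
    n <- case[1]; tr <- case[2]; cutoff <- case[3]
    X <- build_design_matrix(
      tibble::tibble(onset_s = 10, duration_s = 3.5, condition = "A"),
      NULL, n_scans = n, tr_s = tr, hp_cutoff_s = cutoff)
    got <- sum(grepl("^drift_", X$column_labels))
    # independent count: DCT component k has period 2T/k; components with
    # periods at or above the cutoff are retained
    T_s <- n * tr
    expect_equal(got, sum(2 * T_s / seq_len(n) >= cutoff - 1e-9))
  }
  X_inf <- build_design_matrix(
    tibble::tibble(onset_s = 0, duration_s = 3.5, condition = "A"),
    NULL, n_scans = 50, tr_s = 2, hp_cutoff_s = Inf)
  expect_equal(sum(grepl("^drift_", X_inf$column_labels)), 0)
})

test_that("a near-impulse event reproduces the sampled HRF", {
  n <- 40
  X <- build_design_matrix(
    tibble::tibble(onset_s = 0, duration_s = 1e-6, condition = "A"),
    NULL, n_scans = n, tr_s = 2, hp_cutoff_s = Inf)
  col <- X$values[, "A"]
  kern <- canonical_hrf(hrf_params(), dt_s = 2 / 16)
  ref <- kern[seq(1, by = 16, length.out = n)]
  ref[is.na(ref)] <- 0
  expect_gt(cor(col[1:17], ref[1:17]), 0.9999)
})

test_that("design construction validates onsets", {
  ev <- tibble::tibble(onset_s = c(5, 5), duration_s = 3.5,
                       condition = c("A", "B"))
  expect_error(build_design_matrix(ev, NULL, 100, 2), "identical onsets")
  ev2 <- tibble::tibble(onset_s = 500, duration_s = 3.5, condition = "A")
  expect_error(build_design_matrix(ev2, NULL, 100, 2), "scan duration")
})

test_that("OLS recovers exact betas and matches a normal-equations oracle", {
  set.seed(4)
  ev <- tibble::tibble(onset_s = c(5, 30, 62, 90), duration_s = 3.5,
                       condition = c("LT_A", "ST_A", "LT_A", "ST_A"))
  motion <- matrix(rnorm(70 * 6, sd = 0.1), 70)
  des <- build_design_matrix(ev, motion, n_scans = 70, tr_s = 2)
  X <- des$values
  beta_true <- matrix(rnorm(ncol(X) * 50), ncol(X))
  fit0 <- fit_glm(X %*% beta_true, des)
  expect_equal(unname(fit0$betas), unname(beta_true), tolerance = 1e-8)

  # pure-noise voxels: t-values against an independent least-squares oracle
  Y <- matrix(rnorm(70 * 1000), 70)
  fit <- fit_glm(Y, des)
  con <- compute_contrast(fit, long_labels = "LT_A", short_labels = "ST_A")
  w <- rep(0, ncol(X))
  w[match(c("LT_A", "ST_A"), colnames(X))] <- c(1, -1)
  XtXi <- solve(t(X) %*% X)
  b_or <- XtXi %*% t(X) %*% Y
  res_or <- Y - X %*% b_or
  s2_or <- colSums(res_or^2) / (70 - ncol(X))
  t_or <- drop(t(w) %*% b_or) / sqrt(s2_or * drop(t(w) %*% XtXi %*% w))
  expect_equal(unname(con$t), unname(t_or), tolerance = 1e-6)

  # constant data: all task betas zero
  fitc <- fit_glm(matrix(7, 70, 3), des)
  expect_equal(max(abs(fitc$betas[des$task_columns, ])), 0,
               tolerance = 1e-10)
})

test_that("rank deficiency is reported with the collinear column", {
  ev <- tibble::tibble(onset_s = c(5, 30), duration_s = 3.5,
                       condition = c("A", "B"))
  motion <- cbind(rnorm(60), rnorm(60))
  motion <- cbind(motion, motion[, 1])  # duplicate
  des <- build_design_matrix(ev, motion, 60, 2)
  expect_error(fit_glm(matrix(rnorm(60 * 4), 60), des),
               "rank deficient.*motion")
})

test_that("contrast collapses condition estimates and handles empty pairs", {
  set.seed(9)
  ev <- tibble::tibble(
    onset_s = c(4, 22, 41, 60, 80, 101, 121, 140),
    duration_s = 3.5,
    condition = rep(c("LT_A", "LT_B", "ST_A", "ST_B"), 2))
  des <- build_design_matrix(ev, NULL, 90, 2)
  X <- des$values
  B <- matrix(0, ncol(X), 4)
  rownames(B) <- colnames(X)
  B[c("LT_A", "LT_B"), ] <- 2
  B[c("ST_A", "ST_B"), ] <- 1
  con <- compute_contrast(fit_glm(X %*% B, des))
  expect_equal(unname(con$estimate), rep(1, 4), tolerance = 1e-8)

  B2 <- B
  B2[c("LT_A", "LT_B", "ST_A", "ST_B"), ] <- 1
  con2 <- compute_contrast(fit_glm(X %*% B2, des))
  expect_equal(unname(con2$estimate), rep(0, 4), tolerance = 1e-8)

  # one member of the long pair missing: survivor carries weight 1
  ev3 <- ev[ev$condition != "LT_B", ]
  des3 <- build_design_matrix(ev3, NULL, 90, 2)
  X3 <- des3$values
  B3 <- matrix(0, ncol(X3), 2)
  rownames(B3) <- colnames(X3)
  B3["LT_A", ] <- 3
  con3 <- compute_contrast(fit_glm(X3 %*% B3, des3))
  expect_equal(unname(con3$estimate), rep(3, 2), tolerance = 1e-8)
  expect_true("long_side_single_regressor" %in% con3$collapsed_note)
  expect_error(compute_contrast(fit_glm(X3 %*% B3, des3),
                                long_labels = "LT_B"),
               "collapsed side")
})

test_that("nuisance directions do not leak into the task contrast", {
  set.seed(11)
  ev <- tibble::tibble(onset_s = c(5, 30, 62, 90), duration_s = 3.5,
                       condition = c("LT_A", "ST_A", "LT_A", "ST_A"))
  motion <- matrix(rnorm(80 * 6, sd = 0.2), 80)
  des <- build_design_matrix(ev, motion, 80, 2)
  Y <- matrix(rnorm(80 * 20), 80)
  base <- compute_contrast(fit_glm(Y, des), "LT_A", "ST_A")
  nuis_cols <- setdiff(des$column_labels, des$task_columns)
  gamma <- rnorm(length(nuis_cols))
  Y2 <- Y + des$values[, nuis_cols] %*% matrix(gamma, ncol = 1) %*%
    matrix(1, 1, 20)
  shifted <- compute_contrast(fit_glm(Y2, des), "LT_A", "ST_A")
  expect_equal(base$estimate, shifted$estimate, tolerance = 1e-8)

  # residuals orthogonal to drift columns
  fit <- fit_glm(Y, des)
  drift <- des$values[, grepl("^drift_", des$column_labels), drop = FALSE]
  ip <- crossprod(drift, fit$residuals)
  expect_lt(max(abs(ip)), 1e-8 * max(sqrt(colSums(drift^2))) *
              max(sqrt(colSums(fit$residuals^2))))
})

test_that("AR(1) prewhitening still recovers noise-free betas", {
  ev <- tibble::tibble(onset_s = c(5, 30, 62, 90), duration_s = 3.5,
                       condition = c("LT_A", "ST_A", "LT_A", "ST_A"))
  des <- build_design_matrix(ev, NULL, 70, 2)
  X <- des$values
  beta_true <- matrix(rnorm(ncol(X) * 5), ncol(X))
  fit <- fit_glm(X %*% beta_true, des, prewhiten = "ar1")
  expect_equal(unname(fit$betas), unname(beta_true), tolerance = 1e-6)
})
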