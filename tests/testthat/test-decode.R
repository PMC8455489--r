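test_that("feature extraction honours mask size and subject order", {
  dims <- c(6, 6, 6)
  roi <- array(FALSE, dims)
  roi[2:3, 2, 2] <- TRUE
  roi[5, 5, 5] <- TRUE
  roi[1, 6, 3] <- TRUE
  roi[4, 4, 4] <- TRUE
  set.seed(1)
  maps <- lapply(1:10, function(i) array(rnorm(prod(dims)), dims))
  names(maps) <- sprintf("sub-%02d", 10:1)
  X <- extract_features(maps, roi)
  expect_equal(dim(X), c(10, 5))
  expect_equal(rownames(X), sprintf("sub-%02d", 1:10))
  X2 <- extract_features(maps[sample(10)], roi)
  expect_identical(X, X2)
  expect_equal(attr(X, "voxel_index"), which(roi))
})

test_that("full shrinkage collapses to the intercept-only model", {
  set.seed(2)
  X <- matrix(rnorm(30 * 8), 30)
  y <- runif(30, 0.1, 0.9)
  fit <- fit_l1_logistic(X, y, lambda = 10)
  expect_true(all(fit$coef == 0))
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-4)
})

test_that("unpenalised fit matches the Newton MLE oracle", {
  set.seed(3)
  X <- matrix(rnorm(60 * 4), 60)
  y <- plogis(0.3 + X %*% c(0.5, -0.4, 0, 0.2) + rnorm(60, sd = 0.3))
  fit <- fit_l1_logistic(X, y, lambda = 0)
  oracle <- newton_fractional_logit(X, y)
  expect_equal(c(fit$intercept, fit$coef), unname(oracle),
               tolerance = 1e-5)
  expect_error(fit_l1_logistic(cbind(X, NA), y, 0.1), "Non-finite")
})

test_that("sparsity is non-increasing along increasing penalties", {
  set.seed(4)
  n <- 80
  X <- matrix(rnorm(n * 20), n)
  y <- plogis(X %*% c(1, -1, 0.5, rep(0, 17)) + rnorm(n, sd = 0.5))
  grid <- 2^seq(-2, -10, by = -0.5)
  nnz <- vapply(grid, function(l) sum(fit_l1_logistic(X, y, l)$coef != 0),
                numeric(1))
  expect_true(all(diff(nnz) >= 0))  # grid is descending in lambda
})

test_that("a planted informative feature is selected and signed correctly", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    X <- matrix(rnorm(n * 51), n)
    y <- plogis(1.2 * X[, 1] + rnorm(n, sd = 0.5))
    fit <- fit_l1_logistic(X, y, lambda = 2^-10.75)
    hits <- hits + (fit$coef[1] > 0)
  }
  expect_gte(hits, 19)
})

test_that("nested selection shrinks under noise and relaxes under signal", {
  cfg <- decoder_config()
  expect_equal(select_lambda_nested(matrix(rnorm(30), 10), runif(10),
                                    decoder_config(lambda_grid = 0.01)),
               0.01)
  grid <- cfg$lambda_grid
  top <- 0
  for (seed in 1:15) {
    set.seed(seed)
    X <- matrix(rnorm(16 * 12), 16)
    y <- runif(16, 0.2, 0.8)
    lam <- select_lambda_nested(X, y, cfg)
    top <- top + (lam >= grid[4])
  }
  expect_gte(top / 15, 0.8)

  # many weak independent features: the decoder must keep most of them,
  # so the inner loop favours weak penalties
  low <- 0
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 15), 60)
    y <- plogis(drop(X %*% rep(0.4, 15)) + rnorm(60, sd = 0.2))
    lam <- select_lambda_nested(X, y, cfg)
    low <- low + (lam < stats::median(grid))
  }
  expect_gte(low / 10, 0.8)
})

test_that("LOSO predictions never see the held-out outcome", {
  co <- sim_feature_cohort(10, 6, coupling = 1, seed = 5)
  cfg <- decoder_config(lambda_grid = fast_grid)
  r1 <- loso_predict(co$X, co$y, cfg)
  y2 <- co$y
  y2[3] <- 0.99
  r2 <- loso_predict(co$X, y2, cfg)
  expect_equal(r1$predictions$y_pred[3], r2$predictions$y_pred[3])
  expect_error(loso_predict(co$X, rep(0.5, 10), cfg), "constant")
  expect_error(loso_predict(co$X[1:3, ], co$y[1:3], cfg), "at least 4")
})

test_that("standardised decoding is scale equivariant", {
  co <- sim_feature_cohort(12, 8, coupling = 1.5, seed = 6)
  cfg <- decoder_config(lambda_grid = fast_grid)
  r1 <- loso_predict(co$X, co$y, cfg)
  r2 <- loso_predict(co$X * 50, co$y, cfg)
  expect_equal(r1$predictions$y_pred, r2$predictions$y_pred,
               tolerance = 1e-6)
})

test_that("null decoding has near-zero mean correlation", {
  # fixed mid-grid penalty: the inner selector is exercised elsewhere
  rs <- vapply(1:200, function(seed) {
    co <- sim_feature_cohort(12, 8, coupling = 0, seed = 1000 + seed)
    loso_predict(co$X, co$y, decoder_config(lambda_grid = 2^-10))$r
  }, numeric(1))
  se_mean <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se_mean + 0.05)
})

test_that("strong coupling yields high decoding accuracy", {
  ok <- 0
  for (seed in 1:10) {
    co <- sim_feature_cohort(40, 15, coupling = 2.5, seed = 2000 + seed,
                             noise_sd = 0.5)
    res <- loso_predict(co$X, co$y, decoder_config(lambda_grid = 2^-9))
    ok <- ok + (res$r > 0.4)
  }
  expect_gte(ok, 9)
})

test_that("permutation p equals the exhaustive enumeration on tiny n", {
  y <- c(0.11, 0.32, 0.48, 0.63, 0.91)
  res <- permutation_test(list(y_obs = y, y_pred = y), exhaustive = TRUE)
  expect_equal(res$n_perm, 120L)
  expect_equal(res$p, 1 / 120)
  # observed below the null median: p > 0.5
  worst <- permutation_test(list(y_obs = y, y_pred = rev(y)),
                            exhaustive = TRUE)
  expect_gt(worst$p, 0.5)
})

test_that("sampled permutation p agrees with the exhaustive value", {
  set.seed(9)
  y_obs <- runif(6)
  y_pred <- y_obs + rnorm(6, sd = 0.3)
  exact <- permutation_test(list(y_obs = y_obs, y_pred = y_pred),
                            exhaustive = TRUE)
  sampled <- permutation_test(list(y_obs = y_obs, y_pred = y_pred),
                              n_perm = 20000, seed = 4)
  se <- sqrt(exact$p * (1 - exact$p) / 20000)
  expect_lt(abs(sampled$p - exact$p), 4 * se + 1e-4)
  expect_equal(sampled$p_plus_one,
               (sampled$null_exceed_count + 1) / 20001)
})

test_that("k-fold with k = n reproduces leave-one-subject-out", {
  co <- sim_feature_cohort(8, 5, coupling = 1, seed = 7)
  cfg <- decoder_config(lambda_grid = fast_grid)
  loso <- loso_predict(co$X, co$y, cfg)
  kf <- kfold_predict(co$X, co$y, cfg, k = 8)
  expect_equal(sort(kf$predictions$y_pred), sort(loso$predictions$y_pred))
  expect_equal(kf$r, loso$r, tolerance = 1e-12)

  kf2 <- kfold_predict(co$X[1:4, ], co$y[1:4],
                       decoder_config(lambda_grid = fast_grid, seed = 2),
                       k = 2)
  expect_length(kf2$predictions$y_pred, 4)
  expect_true(all(is.finite(kf2$predictions$y_pred)))
})

test_that("per-ROI baselines locate the informative region", {
  dims <- c(8, 8, 8)
  roiA <- array(FALSE, dims); roiA[2:3, 2:3, 2] <- TRUE
  roiB <- array(FALSE, dims); roiB[6:7, 6:7, 6] <- TRUE
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    z <- rnorm(n)
    y <- plogis(1.5 * z)
    maps <- lapply(seq_len(n), function(i) {
      m <- array(rnorm(prod(dims), sd = 0.6), dims)
      m[roiA] <- m[roiA] + z[i]
      m
    })
    names(maps) <- sprintf("sub-%02d", seq_len(n))
    tab <- univariate_baseline(maps, list(A = roiA, B = roiB), y,
                               run_mvpa = FALSE)
    wins <- wins + (abs(tab$r_univariate[1]) > abs(tab$r_univariate[2]))
  }
  expect_gte(wins, 9)

  # single-voxel ROI mean equals the voxel value
  roi1 <- array(FALSE, dims); roi1[4, 4, 4] <- TRUE
  maps1 <- lapply(1:6, function(i) array(i, dims))
  names(maps1) <- sprintf("sub-%02d", 1:6)
  tab1 <- univariate_baseline(maps1, list(one = roi1),
                              y = plogis(1:6 / 4), run_mvpa = FALSE)
  expect_equal(tab1$n_voxels, 1)
})
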