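#' Decoder configuration
#'
#' @param lambda_grid L1 penalty grid, default `2^-8` down to `2^-13.5` in
#'   half-powers (12 values), kept sorted descending.
#' @param cv_scheme `"loso"` or `"kfold"`.
#' @param k Fold count when `cv_scheme = "kfold"`.
#' @param inner_criterion Held-out criterion of the nested loop:
#'   `"deviance"` (binomial, default) or `"mse"`.
#' @param standardize Standardise features within each training set?
#' @param seed Seed for fold assignment in k-fold mode.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(lambda_grid = 2^seq(-8, -13.5, by = -0.5),
                           cv_scheme = c("loso", "kfold"), k = NULL,
                           inner_criterion = c("deviance", "mse"),
                           standardize = TRUE, seed = 1L) {
  cv_scheme <- match.arg(cv_scheme)
  inner_criterion <- match.arg(inner_criterion)
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  if (any(lambda_grid < 0)) abort("`lambda_grid` must be nonnegative.")
  if (cv_scheme == "kfold") {
    if (is.null(k)) abort("`k` is required for the k-fold scheme.")
    assert_count(k, "k", min = 2L)
  }
  structure(list(lambda_grid = lambda_grid, cv_scheme = cv_scheme,
                 k = if (is.null(k)) NULL else as.integer(k),
                 inner_criterion = inner_criterion,
                 standardize = standardize, seed = as.integer(seed)),
            class = "decoder_config")
}

#' Extract the ROI feature matrix from contrast maps
#'
#' One row per subject (sorted by subject id when names are supplied), one
#' column per ROI voxel in canonical (linear index) order.
#'
#' @param contrast_maps Named list of `contrast_map` objects or 3-D arrays.
#' @param roi Logical ROI volume (e.g. from [clusters_to_roi()]).
#' @return Matrix with `voxel_index` attribute; rownames are subject ids.
#' @export
extract_features <- function(contrast_maps, roi) {
  vox <- which(roi)
  if (!length(vox)) abort("ROI mask is empty.")
  ids <- names(contrast_maps) %||% sprintf("sub-%02d",
                                           seq_along(contrast_maps))
  ord <- order(ids)
  rows <- lapply(contrast_maps[ord], function(m) {
    v <- if (inherits(m, "contrast_map")) m$values else m
    if (!same_grid(v, roi)) abort("Contrast map and ROI grids differ.")
    as.vector(v)[vox]
  })
  X <- do.call(rbind, rows)
  if (anyNA(X)) abort("NaN feature values inside the ROI.")
  rownames(X) <- ids[ord]
  attr(X, "voxel_index") <- vox
  X
}

# glmnet wrapper: fractional-response binomial lasso over a descending
# lambda path; pads single-column problems with a zero column. The path
# coefficients are extracted once so prediction avoids S4 dispatch in the
# cross-validation hot loops.
l1_path <- function(X, y, lambdas, weights = NULL) {
  padded <- ncol(X) == 1L
  if (padded) X <- cbind(X, pad = 0)
  fit <- glmnet::glmnet(X, cbind(1 - y, y), family = "binomial",
                        lambda = lambdas, standardize = FALSE,
                        weights = weights, thresh = 1e-9, maxit = 1e5)
  list(fit = fit, padded = padded, lambda = fit$lambda,
       a0 = as.numeric(fit$a0), beta = as.matrix(fit$beta))
}

# response-scale predictions for every lambda on the fitted path
l1_path_predict <- function(path, Xnew) {
  if (path$padded) Xnew <- cbind(Xnew, 0)
  eta <- sweep(Xnew %*% path$beta, 2, path$a0, "+")
  matrix(plogis(eta), nrow = nrow(Xnew),
         dimnames = list(NULL, NULL))
}

# intercept + coefficients at the path entry closest to `lambda`
l1_path_coef <- function(path, lambda) {
  j <- which.min(abs(path$lambda - lambda))
  b <- unname(c(path$a0[j], path$beta[, j]))
  if (path$padded) b <- b[-length(b)]
  b
}

#' Fit an L1-regularised logistic regression at a single penalty
#'
#' Minimises the mean binomial deviance of the fractional responses plus
#' `lambda * sum(|coef|)` with an unpenalised intercept (the standard
#' lasso-GLM objective). Deterministic given its inputs.
#'
#' @param X Feature matrix.
#' @param y Outcome probabilities in `[0, 1]`.
#' @param lambda Penalty (>= 0).
#' @param weights Optional observation weights (e.g. conflict counts).
#' @return List with `intercept`, `coef`, `lambda`.
#' @export
fit_l1_logistic <- function(X, y, lambda, weights = NULL) {
  if (anyNA(X) || any(!is.finite(X))) abort("Non-finite feature values.")
  assert_prob(y, "y")
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  lam_seq <- if (lambda > 0) lambda * c(16, 8, 4, 2, 1) else
    c(0.08, 0.02, 0.005, 0.001, 0)
  p <- l1_path(X, y, lam_seq, weights)
  b <- l1_path_coef(p, lambda)
  list(intercept = b[1], coef = b[-1], lambda = lambda)
}

inner_criterion_value <- function(y, prob, criterion) {
  eps <- 1e-12
  prob <- pmin(1 - eps, pmax(eps, prob))
  if (criterion == "deviance") {
    -2 * (y * log(prob) + (1 - y) * log(1 - prob))
  } else {
    (y - prob)^2
  }
}

standardizer <- function(X_train, on) {
  if (!on) {
    return(list(apply = identity))
  }
  n <- nrow(X_train)
  mu <- colMeans(X_train)
  s <- sqrt(pmax(colSums(X_train^2) - n * mu^2, 0) / (n - 1))
  s[s == 0 | !is.finite(s)] <- 1
  list(apply = function(X) t((t(X) - mu) / s))
}

#' Select the L1 penalty by nested cross-validation on the training set
#'
#' Runs an inner leave-one-out loop over the training subjects: for every
#' grid value, the held-out criterion (binomial deviance by default) of the
#' inner predictions is accumulated; the minimising grid value is returned,
#' ties resolved toward the largest (sparsest) penalty.
#'
#' @param X_train,y_train Training features and outcomes.
#' @param cfg A [decoder_config()].
#' @param weights Optional observation weights.
#' @return The selected lambda (scalar).
#' @export
select_lambda_nested <- function(X_train, y_train, cfg = decoder_config(),
                                 weights = NULL) {
  grid <- cfg$lambda_grid
  if (length(grid) == 1L) return(grid)
  n <- nrow(X_train)
  if (n < 3L) abort("Nested selection needs at least 3 training subjects.")
  crit <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    std <- standardizer(X_train[-i, , drop = FALSE], cfg$standardize)
    Xi <- std$apply(X_train[-i, , drop = FALSE])
    p <- l1_path(Xi, y_train[-i], grid, weights[-i])
    Xh <- std$apply(X_train[i, , drop = FALSE])
    prob <- drop(l1_path_predict(p, Xh))
    # a diverging path may stop early; unfitted grid values stay NA
    k <- length(p$lambda)
    crit[i, seq_len(k)] <- inner_criterion_value(y_train[i],
                                                 prob[seq_len(k)],
                                                 cfg$inner_criterion)
  }
  total <- colSums(crit)
  total[is.na(total)] <- Inf
  grid[which(total <= min(total) + 1e-12)[1]]
}

# Shared engine for LOSO and k-fold prediction.
cv_predict_engine <- function(X, y, folds, cfg, weights = NULL) {
  n <- nrow(X)
  y_pred <- rep(NA_real_, n)
  lambda_used <- rep(NA_real_, n)
  fold_of <- rep(NA_integer_, n)
  coefs <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    std <- standardizer(X[train, , drop = FALSE], cfg$standardize)
    Xt <- std$apply(X[train, , drop = FALSE])
    # the nested loop needs >= 3 training subjects; below that fall back
    # to the sparsest grid value
    lam <- if (length(train) >= 3L) {
      select_lambda_nested(X[train, , drop = FALSE], y[train], cfg,
                           weights[train])
    } else {
      cfg$lambda_grid[1]
    }
    fitp <- l1_path(Xt, y[train], cfg$lambda_grid, weights[train])
    Xh <- std$apply(X[test, , drop = FALSE])
    j <- which.min(abs(fitp$lambda - lam))
    y_pred[test] <- l1_path_predict(fitp, Xh)[, j]
    lambda_used[test] <- lam
    fold_of[test] <- f
    coefs[[f]] <- l1_path_coef(fitp, lam)
  }
  predictions <- tibble(
    subject_id = rownames(X) %||% sprintf("sub-%02d", seq_len(n)),
    y_obs = y, y_pred = y_pred, fold = fold_of, lambda = lambda_used
  )
  structure(
    list(predictions = predictions,
         r = cor(y_pred, y), rmse = sqrt(mean((y_pred - y)^2)),
         chosen_lambda = vapply(folds, function(f) lambda_used[f[1]],
                                numeric(1)),
         coefficients = coefs, config = cfg),
    class = "decoding_result"
  )
}

#' Leave-one-subject-out decoding of the failure probability
#'
#' For each subject: exclude them, standardise features on the remaining
#' subjects, select the L1 penalty by nested leave-one-out cross-validation
#' on those subjects, fit, and predict the held-out subject's failure
#' probability. Performance is the Pearson correlation and RMSE between
#' cross-validated predictions and observed probabilities.
#'
#' @param X Feature matrix (subjects x ROI voxels).
#' @param y Observed failure probabilities.
#' @param cfg A [decoder_config()].
#' @param weights Optional observation weights.
#' @return An object of class `decoding_result`.
#' @export
loso_predict <- function(X, y, cfg = decoder_config(), weights = NULL) {
  if (nrow(X) < 4L) abort("Need at least 4 subjects.")
  if (sd(y) == 0) abort("Outcome is constant; correlation undefined.")
  cv_predict_engine(X, y, as.list(seq_len(nrow(X))), cfg, weights)
}

#' k-fold variant of the decoding analysis
#'
#' Folds are seeded and stratified by outcome quantile. With `k = n` this
#' reduces exactly to [loso_predict()].
#'
#' @inheritParams loso_predict
#' @param k Number of folds (>= 2); defaults to `cfg$k`.
#' @return An object of class `decoding_result`.
#' @export
kfold_predict <- function(X, y, cfg = NULL, k = NULL, weights = NULL) {
  if (is.null(k)) k <- cfg$k
  if (is.null(k)) abort("`k` must be given (directly or via `cfg`).")
  if (is.null(cfg)) cfg <- decoder_config(cv_scheme = "kfold", k = k)
  n <- nrow(X)
  assert_count(k, "k", min = 2L)
  if (sd(y) == 0) abort("Outcome is constant; correlation undefined.")
  set.seed(cfg$seed)
  # stratify: walk subjects in outcome order, deal into folds round-robin
  ord <- order(y, runif(n))
  fold_id <- integer(n)
  fold_id[ord] <- rep_len(sample.int(k), n)
  folds <- split(seq_len(n), fold_id)
  cv_predict_engine(X, y, folds, cfg, weights)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Permutation test of the prediction-outcome correlation
#'
#' Permutes the cross-validated predictions and re-correlates with the
#' observed outcomes; the p-value is the fraction of null correlations
#' greater than or equal to the observed one. When that count is zero the
#' result reports `p_label = "< 1/n_perm"` alongside the raw 0; the
#' `(b+1)/(m+1)` estimator is reported as `p_plus_one`.
#'
#' @param result A `decoding_result`, or a list/tibble with `y_obs` and
#'   `y_pred`.
#' @param n_perm Number of permutations (>= 100), default one million.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `n!` permutations instead of sampling.
#' @param keep_null Return the null correlations (for plotting)?
#' @return Object of class `permutation_result`.
#' @export
permutation_test <- function(result, n_perm = 1e6, seed = 1L,
                             exhaustive = FALSE, keep_null = FALSE) {
  d <- if (inherits(result, "decoding_result")) result$predictions else
    as.data.frame(result)
  y_obs <- d$y_obs
  y_pred <- d$y_pred
  if (sd(y_obs) == 0 || sd(y_pred) == 0) {
    abort("Constant predictions or outcomes; correlation undefined.")
  }
  n <- length(y_obs)
  obs_r <- cor(y_pred, y_obs)
  xc <- y_obs - mean(y_obs)
  yc <- y_pred - mean(y_pred)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (exhaustive) {
    perms <- all_permutations(n)
    null_r <- as.vector((perms_apply(yc, perms) %*% xc) / denom)
    n_perm <- nrow(perms)
  } else {
    if (n_perm < 100) abort("`n_perm` must be at least 100.")
    set.seed(seed)
    null_r <- vapply(seq_len(n_perm),
                     function(i) sum(yc[sample.int(n)] * xc) / denom,
                     numeric(1))
  }
  b <- sum(null_r >= obs_r)
  structure(
    list(n_perm = as.integer(n_perm), observed_r = obs_r,
         null_exceed_count = b, p = b / n_perm,
         p_plus_one = (b + 1) / (n_perm + 1),
         p_label = if (b == 0) sprintf("< 1/%d", as.integer(n_perm)) else
           format(b / n_perm),
         null_r = if (keep_null) null_r else NULL),
    class = "permutation_result"
  )
}

perms_apply <- function(yc, perms) {
  matrix(yc[perms], nrow = nrow(perms))
}

#' Per-ROI univariate and multivariate baselines
#'
#' For each labelled ROI: the subjectwise mean contrast value and its
#' Pearson correlation with the outcome, plus (optionally) a per-ROI
#' decoding run restricted to that ROI's voxels.
#'
#' @param contrast_maps Named list of contrast maps or 3-D arrays.
#' @param roi A `roi_mask` with a `cluster_id` attribute, or a list of
#'   logical volumes.
#' @param y Outcome probabilities (subject order of `contrast_maps` after
#'   id sorting).
#' @param cfg A [decoder_config()] for the per-ROI decoding.
#' @param run_mvpa Also run [loso_predict()] per ROI?
#' @return Tibble: `roi_id`, `n_voxels`, `r_univariate`, and when requested
#'   `r_mvpa`, `rmse_mvpa`.
#' @export
univariate_baseline <- function(contrast_maps, roi, y,
                                cfg = decoder_config(), run_mvpa = TRUE) {
  masks <- if (is.list(roi) && !inherits(roi, "roi_mask")) {
    roi
  } else {
    ids <- attr(roi, "cluster_id")
    if (is.null(ids)) {
      list(`1` = roi)
    } else {
      lapply(sort(unique(ids[ids > 0])), function(k) {
        m <- array(ids == k, dim = dim(roi))
        m
      })
    }
  }
  purrr::imap_dfr(masks, function(m, nm) {
    X <- extract_features(contrast_maps, m)
    means <- rowMeans(X)
    row <- tibble(roi_id = as.character(nm), n_voxels = ncol(X),
                  r_univariate = if (sd(means) > 0 && sd(y) > 0)
                    cor(means, y) else NA_real_)
    if (run_mvpa && nrow(X) >= 4L) {
      res <- loso_predict(X, y, cfg)
      row$r_mvpa <- res$r
      row$rmse_mvpa <- res$rmse
    }
    row
  })
}
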