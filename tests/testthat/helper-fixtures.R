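# Shared fixture builders (all data generated in code).

# Fast BOLD-capable config: small grid, short paradigm.
tiny_cfg <- function(...) {
  sim_config(n_subjects = 6, grid_dims = c(10, 10, 10), n_items = 6,
             n_reps = 2, seed = 42, ...)
}

# Hand-built ratings table.
ratings_tbl <- function(short, long) {
  tibble::tibble(item_id = sprintf("item%03d", seq_along(short)),
                 short_term = as.integer(short), long_term = as.integer(long))
}

# Hand-built trials for one subject.
trials_tbl <- function(item_id, decision, missed = NULL) {
  n <- length(item_id)
  if (is.null(missed)) missed <- is.na(decision)
  tibble::tibble(trial_index = seq_len(n), item_id = item_id,
                 onset_s = (seq_len(n) - 1) * 9.5, duration_s = 3.5,
                 decision = as.integer(decision), missed = missed)
}

# Feature-level cohort with a latent score coupled to the outcome: every
# feature carries the subject score plus feature noise, mimicking ROI
# contrast features whose shared amplitude tracks failure probability.
sim_feature_cohort <- function(n, p, coupling, seed, noise_sd = 1) {
  set.seed(seed)
  z <- rnorm(n)
  X <- matrix(z, n, p) + matrix(rnorm(n * p, sd = noise_sd), n, p)
  # outcome carries its own measurement noise (EMA sampling error analogue)
  y <- plogis(qlogis(0.53) + coupling * z + rnorm(n, sd = 0.4))
  rownames(X) <- sprintf("sub-%02d", seq_len(n))
  list(X = X, y = y, z = z)
}

fast_grid <- 2^seq(-8, -13.5, by = -1)  # thinned lambda grid for speed
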