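#' Simulate consequence ratings for the preference task items
#'
#' Each item receives a short-term and a long-term consequence rating on the
#' six-point scale `{-3, -2, -1, 1, 2, 3}` (no neutral point). With
#' probability `cfg$divergence_frac` the two ratings are given opposite
#' signs (a "divergent" item — the self-control-relevant case); otherwise
#' both are positive or both negative with equal probability. Magnitudes are
#' uniform on `{1, 2, 3}`.
#'
#' @param cfg A [sim_config()].
#' @param subject_seed Integer seed for this subject's ratings.
#' @return A tibble with columns `item_id`, `short_term`, `long_term`.
#' @export
simulate_ratings <- function(cfg, subject_seed) {
  assert_prob(cfg$divergence_frac, "divergence_frac")
  n <- cfg$n_items
  set.seed(subject_seed)
  divergent <- runif(n) < cfg$divergence_frac
  s_short <- ifelse(runif(n) < 0.5, 1L, -1L)
  s_long <- ifelse(divergent, -s_short, s_short)
  tibble(
    item_id = sprintf("item%03d", seq_len(n)),
    short_term = s_short * sample(1:3, n, replace = TRUE),
    long_term = s_long * sample(1:3, n, replace = TRUE)
  )
}

#' Simulate trial-level preference decisions with onsets
#'
#' Builds the `n_items * n_reps` trial sequence (items shuffled within each
#' repetition block), accumulates onsets as stimulus duration plus a sampled
#' interstimulus interval, and draws each decision on the four-point scale
#' `{-2, -1, 1, 2}` (negative = decline). On divergent items the probability
#' of a long-term-consistent choice is
#' `plogis(cfg$decision_slope * latent_self_control)`; on congruent items
#' acceptance follows the mean rated value. A missed trial (probability
#' `miss_prob`) has `decision = NA`.
#'
#' @param ratings Tibble from [simulate_ratings()].
#' @param latent_self_control Subject's latent self-control (logit scale).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param miss_prob Per-trial miss probability; defaults to `cfg$miss_prob`.
#' @return A tibble with columns `trial_index`, `item_id`, `onset_s`,
#'   `duration_s`, `decision`, `missed`.
#' @export
simulate_decisions <- function(ratings, latent_self_control, cfg, seed,
                               miss_prob = cfg$miss_prob) {
  if (nrow(ratings) == 0L) abort("`ratings` must be nonempty.")
  assert_prob(miss_prob, "miss_prob")
  set.seed(seed)
  order_idx <- unlist(lapply(seq_len(cfg$n_reps),
                             function(r) sample.int(nrow(ratings))))
  r <- ratings[order_idx, ]
  n <- nrow(r)
  isi <- sample(cfg$isi_choices_s, n, replace = TRUE)
  # onset_{k+1} = onset_k + stim_dur + isi_k; first trial starts at 0
  onsets <- c(0, cumsum(cfg$stim_dur_s + isi))[seq_len(n)]

  divergent <- sign(r$short_term) != sign(r$long_term)
  p_lt <- plogis(cfg$decision_slope * latent_self_control)
  lt_choice <- runif(n) < p_lt
  # long-term-consistent means following the sign of the long-term rating;
  # on congruent items preference follows the (shared-sign) mean value
  accept <- ifelse(
    divergent,
    ifelse(lt_choice, r$long_term > 0, r$long_term < 0),
    runif(n) < plogis(0.6 * (r$short_term + r$long_term) / 2)
  )
  strength <- sample(1:2, n, replace = TRUE)
  decision <- ifelse(accept, strength, -strength)
  missed <- runif(n) < miss_prob
  decision[missed] <- NA_integer_

  tibble(
    trial_index = seq_len(n),
    item_id = r$item_id,
    onset_s = onsets,
    duration_s = cfg$stim_dur_s,
    decision = as.integer(decision),
    missed = missed
  )
}
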