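#' Simulate one subject's ecological momentary assessment records
#'
#' Emits one row per issued alarm. An alarm is answered with probability
#' `p_respond`; an answered alarm reports a desire with probability
#' `p_desire`; a desire is conflict-laden with probability `p_conflict`;
#' a conflict-laden desire is enacted (a real-life self-control failure)
#' with probability `true_p_fail`. Desire/conflict strengths are uniform on
#' 1-6 and the desire type uniform over 19 categories; fields below an
#' unreached branch are `NA` (serialised as `"n/a"`).
#'
#' @param true_p_fail Subject's true failure probability in (0, 1).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `alarm_index`, `answered`, `desire`,
#'   `desire_strength`, `desire_type`, `conflict`, `conflict_strength`,
#'   `resisted`, `enacted`.
#' @export
simulate_ema <- function(true_p_fail, cfg, seed) {
  if (!is.numeric(true_p_fail) || true_p_fail <= 0 || true_p_fail >= 1) {
    abort("`true_p_fail` must lie strictly inside (0, 1).")
  }
  set.seed(seed)
  n <- cfg$n_alarms
  answered <- runif(n) < cfg$p_respond
  desire <- answered & runif(n) < cfg$p_desire
  conflict <- desire & runif(n) < cfg$p_conflict
  enacted <- conflict & runif(n) < true_p_fail
  resisted <- conflict & runif(n) < 0.5

  na_if_not <- function(flag, values) ifelse(flag, values, NA)
  tibble(
    alarm_index = seq_len(n),
    answered = answered,
    desire = na_if_not(answered, desire),
    desire_strength = as.integer(na_if_not(desire, sample(1:6, n, TRUE))),
    desire_type = as.integer(na_if_not(desire, sample(1:19, n, TRUE))),
    conflict = na_if_not(desire, conflict),
    conflict_strength = as.integer(na_if_not(conflict, sample(1:6, n, TRUE))),
    resisted = na_if_not(conflict, resisted),
    enacted = na_if_not(conflict, enacted)
  )
}
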