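ema_cols <- c("subject_id", "alarm_index", "answered", "desire",
              "desire_strength", "desire_type", "conflict",
              "conflict_strength", "resisted", "enacted")

#' Read / write EMA records as TSV
#'
#' One row per issued alarm; missing values encoded `"n/a"`. Reading
#' validates the conditional structure (conflict fields only under a
#' desire, enactment only under a conflict, strengths in 1-6) and names the
#' offending rows.
#'
#' @param path File path.
#' @return A tibble of EMA records.
#' @export
read_ema_tsv <- function(path) {
  x <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                       col_types = readr::cols(
                         subject_id = "c", alarm_index = "i", answered = "l",
                         desire = "l", desire_strength = "i",
                         desire_type = "i", conflict = "l",
                         conflict_strength = "i", resisted = "l",
                         enacted = "l"))
  validate_ema(x)
}

#' @rdname read_ema_tsv
#' @param records A tibble of EMA records.
#' @export
write_ema_tsv <- function(records, path) {
  readr::write_tsv(records[, intersect(ema_cols, names(records))], path,
                   na = "n/a")
  invisible(path)
}

#' Validate EMA records
#'
#' @param records Tibble with the EMA columns.
#' @return The validated tibble (invisibly unchanged).
#' @export
validate_ema <- function(records) {
  bad_conflict <- which(isTRUE_v(records$conflict) & !isTRUE_v(records$desire))
  if (length(bad_conflict)) {
    abort(sprintf("Conflict reported without a desire at row(s): %s",
                  paste(bad_conflict, collapse = ", ")))
  }
  bad_enact <- which((isTRUE_v(records$enacted) | isTRUE_v(records$resisted)) &
                       !isTRUE_v(records$conflict))
  if (length(bad_enact)) {
    abort(sprintf("Enactment/resistance reported without a conflict at row(s): %s",
                  paste(bad_enact, collapse = ", ")))
  }
  for (s in c("desire_strength", "conflict_strength")) {
    v <- records[[s]]
    bad <- which(!is.na(v) & !(v %in% 1:6))
    if (length(bad)) {
      abort(sprintf("`%s` outside 1-6 at row(s): %s", s,
                    paste(bad, collapse = ", ")))
    }
  }
  records
}

isTRUE_v <- function(x) !is.na(x) & x

#' Summarise one subject's EMA records
#'
#' Counts answered alarms, desires, conflicts and enacted conflicts
#' (self-control failures), and computes the subject's probability of a
#' real-life self-control failure as failures / conflicts. With zero
#' conflicts the probability is undefined (`NA`) and the subject flagged.
#'
#' @param records EMA tibble for a single subject.
#' @return One-row tibble: `subject_id`, `n_answered`, `n_desires`,
#'   `n_conflicts`, `n_failures`, `p_scf`, `p_scf_defined`.
#' @export
summarize_ema <- function(records) {
  if (length(unique(records$subject_id %||% "s")) > 1L) {
    abort("`records` must belong to a single subject.")
  }
  validate_ema(records)
  n_conf <- sum(isTRUE_v(records$conflict))
  n_fail <- sum(isTRUE_v(records$enacted))
  tibble(
    subject_id = records$subject_id[1] %||% NA_character_,
    n_answered = sum(isTRUE_v(records$answered)),
    n_desires = sum(isTRUE_v(records$desire)),
    n_conflicts = n_conf,
    n_failures = n_fail,
    p_scf = if (n_conf > 0) n_fail / n_conf else NA_real_,
    p_scf_defined = n_conf > 0
  )
}

#' Summarise every subject of a cohort
#'
#' @param records EMA tibble with a `subject_id` column.
#' @return Tibble with one [summarize_ema()] row per subject.
#' @export
summarize_ema_cohort <- function(records) {
  records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_split() |>
    purrr::map(summarize_ema) |>
    dplyr::bind_rows()
}

#' Apply the EMA-level subject exclusion rules
#'
#' Removes subjects with zero reported conflicts (failure probability
#' undefined) and subjects with incomplete EMA acquisition, operationalised
#' as fewer answered alarms than `min_answered`. Every exclusion is logged
#' with its reason.
#'
#' @param summaries Tibble from [summarize_ema_cohort()].
#' @param min_answered Minimum answered alarms to count as complete.
#' @return List with `included` (tibble of retained summaries) and
#'   `exclusion_log` (tibble `subject_id`, `reason`).
#' @export
apply_ema_exclusions <- function(summaries, min_answered = 1L) {
  log <- dplyr::bind_rows(
    summaries |>
      dplyr::filter(.data$n_answered < min_answered) |>
      dplyr::transmute(.data$subject_id, reason = "incomplete_ema"),
    summaries |>
      dplyr::filter(.data$n_answered >= min_answered,
                    .data$n_conflicts == 0L) |>
      dplyr::transmute(.data$subject_id, reason = "zero_conflicts")
  )
  list(
    included = dplyr::filter(summaries,
                             !.data$subject_id %in% log$subject_id),
    exclusion_log = log
  )
}
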