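#' Classify items by the sign structure of their consequence ratings
#'
#' An item is divergent when its anticipated short-term and long-term
#' consequence ratings carry opposite signs — the configuration in which a
#' preference decision can be long-term- or short-term-consistent at all.
#'
#' @param ratings Tibble with columns `item_id`, `short_term`, `long_term`,
#'   values in `{-3, -2, -1, 1, 2, 3}`.
#' @return The input with an added factor column `item_class`, levels
#'   `DIVERGENT`, `CONGRUENT_POS`, `CONGRUENT_NEG`.
#' @export
classify_items <- function(ratings) {
  st <- ratings$short_term
  lt <- ratings$long_term
  bad <- which(!(st %in% c(-3:-1, 1:3)) | !(lt %in% c(-3:-1, 1:3)))
  if (length(bad)) {
    abort(sprintf(
      "Ratings must lie in {-3,-2,-1,1,2,3} (six-point scale, no zero); offending item row(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  cls <- ifelse(sign(st) != sign(lt), "DIVERGENT",
                ifelse(st > 0, "CONGRUENT_POS", "CONGRUENT_NEG"))
  dplyr::mutate(ratings, item_class = factor(
    cls, levels = c("DIVERGENT", "CONGRUENT_POS", "CONGRUENT_NEG")))
}

trial_class_levels <- c("LT_A", "LT_B", "ST_A", "ST_B",
                        "ALLPOS_ENACT", "ALLNEG_NOENACT",
                        "ALLPOS_NOENACT", "ALLNEG_ENACT", "MISSED")

#' Assign each trial to one of the eight decision regressor categories
#'
#' Crossing the item's rating sign pattern with accept/decline yields eight
#' categories: declining a positive-short/negative-long item (`LT_A`) or
#' accepting a negative-short/positive-long item (`LT_B`) are decisions in
#' line with long-term consequences; the mirror cases (`ST_A`, `ST_B`) are
#' in line with short-term consequences; congruent items split into
#' enactment/no-enactment of all-positive/all-negative options. Missed
#' trials get `MISSED`. Classification is per trial: repetitions of one item
#' may land in different categories when the decisions differ.
#'
#' @param trials Tibble with columns `item_id`, `decision`
#'   (`{-2,-1,1,2}` or `NA`), `missed`.
#' @param ratings Tibble accepted by [classify_items()].
#' @return `trials` with added columns `item_class` and `trial_class`.
#' @export
classify_trials <- function(trials, ratings) {
  rated <- classify_items(ratings)
  x <- dplyr::left_join(trials, rated, by = "item_id")
  if (anyNA(x$short_term)) abort("Some trials reference unrated items.")
  ok <- x$missed | x$decision %in% c(-2L, -1L, 1L, 2L)
  if (!all(ok)) {
    abort(sprintf("Invalid decision value on trial row(s): %s",
                  paste(which(!ok), collapse = ", ")))
  }
  accept <- !x$missed & x$decision > 0
  sp <- x$short_term > 0
  lp <- x$long_term > 0
  lab <- dplyr::case_when(
    x$missed ~ "MISSED",
    sp & !lp & !accept ~ "LT_A",
    !sp & lp & accept ~ "LT_B",
    sp & !lp & accept ~ "ST_A",
    !sp & lp & !accept ~ "ST_B",
    sp & lp & accept ~ "ALLPOS_ENACT",
    !sp & !lp & !accept ~ "ALLNEG_NOENACT",
    sp & lp & !accept ~ "ALLPOS_NOENACT",
    !sp & !lp & accept ~ "ALLNEG_ENACT"
  )
  dplyr::mutate(x, trial_class = factor(lab, levels = trial_class_levels))
}

#' Collapse regressor categories to the long-term / short-term decision sets
#'
#' @param trial_class Factor of trial classes.
#' @return Character vector: `"LONG"` for `LT_A`/`LT_B`, `"SHORT"` for
#'   `ST_A`/`ST_B`, `"OTHER"` for the congruent categories, `"MISSED"`.
#' @export
collapse_classes <- function(trial_class) {
  dplyr::case_when(
    trial_class %in% c("LT_A", "LT_B") ~ "LONG",
    trial_class %in% c("ST_A", "ST_B") ~ "SHORT",
    trial_class == "MISSED" ~ "MISSED",
    TRUE ~ "OTHER"
  )
}

#' Apply the task-level subject exclusion rules
#'
#' A subject is excluded for (a) more than 15% missed trials (for the
#' 120-trial design: more than 18; exactly 18 is retained), (b) any run of
#' more than 9 consecutive missed trials, or (c) a floor/ceiling pattern —
#' an empty collapsed LONG or SHORT decision set, which leaves the
#' long > short contrast undefined.
#'
#' @param classified Tibble from [classify_trials()], one subject.
#' @param n_trials Nominal trial count of the design (defaults to the number
#'   of rows).
#' @return A list with `included` (flag) and `reasons` (character vector,
#'   empty when included).
#' @export
apply_task_exclusions <- function(classified, n_trials = nrow(classified)) {
  miss <- classified$trial_class == "MISSED"
  reasons <- character()
  if (sum(miss) > 0.15 * n_trials) reasons <- c(reasons, "missed_gt_15pct")
  runs <- rle(as.logical(miss))
  if (any(runs$lengths[runs$values] > 9L)) {
    reasons <- c(reasons, "missed_gt_9_consecutive")
  }
  coll <- collapse_classes(classified$trial_class)
  if (!any(coll == "LONG")) reasons <- c(reasons, "floor_no_long_trials")
  if (!any(coll == "SHORT")) reasons <- c(reasons, "ceiling_no_short_trials")
  list(included = length(reasons) == 0L, reasons = reasons)
}

#' Cohort-level behavioural descriptives
#'
#' Per-subject and mean counts of divergent trials, long-term-consistent and
#' short-term-consistent decisions, and misses; optionally the correlation
#' of the short-term decision count with the EMA failure probability and
#' with a trait self-control score.
#'
#' @param cohort Tibble of classified trials with a `subject_id` column.
#' @param p_scf Optional named vector (by subject) of EMA failure
#'   probabilities.
#' @param trait Optional named vector of trait self-control scores.
#' @return A list with `per_subject` (tibble), `means` (tibble row) and
#'   `correlations` (tibble; `NA` estimates flagged `undefined` when a
#'   variance is zero).
#' @export
behavioral_descriptives <- function(cohort, p_scf = NULL, trait = NULL) {
  per <- cohort |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_divergent = sum(.data$item_class == "DIVERGENT"),
      n_long = sum(collapse_classes(.data$trial_class) == "LONG"),
      n_short = sum(collapse_classes(.data$trial_class) == "SHORT"),
      n_missed = sum(.data$trial_class == "MISSED"),
      .groups = "drop"
    )
  means <- dplyr::summarise(
    per,
    mean_divergent = mean(.data$n_divergent),
    pct_divergent = 100 * mean(.data$n_divergent / .data$n_trials),
    mean_long = mean(.data$n_long),
    mean_short = mean(.data$n_short),
    mean_missed = mean(.data$n_missed)
  )
  cor_row <- function(label, y) {
    y <- y[match(per$subject_id, names(y))]
    defined <- sd(per$n_short) > 0 && sd(y, na.rm = TRUE) > 0
    tibble(
      measure = label,
      r = if (defined) cor(per$n_short, y, use = "complete.obs") else NA_real_,
      undefined = !defined
    )
  }
  correlations <- dplyr::bind_rows(
    if (!is.null(p_scf)) cor_row("n_short_vs_p_scf", p_scf),
    if (!is.null(trait)) cor_row("n_short_vs_trait", trait)
  )
  list(per_subject = per, means = means, correlations = correlations)
}
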