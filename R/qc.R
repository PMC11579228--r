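#' Flag a main trial's validity
#'
#' A trial counts as engaged-with only when the participant actually moved
#' the dial (non-empty delay trace) and the app logged at least five
#' heart-rate values. Trials failing either check are removed before scoring.
#'
#' @param trial A non-practice [pat_trial()].
#' @param min_hr_samples Minimum heart-rate sample count for validity
#'   (default 5, i.e. trials with four or fewer samples are dropped).
#' @return One of `"valid"`, `"zero_delays"`, `"too_few_hr"` (zero_delays
#'   takes precedence when both fail).
#' @export
flag_trial <- function(trial, min_hr_samples = 5) {
  if (isTRUE(trial$is_practice)) {
    stop("flag_trial() is defined for main trials only; got a practice trial",
         call. = FALSE)
  }
  if (length(trial$delay_trace) == 0) return("zero_delays")
  if (length(trial$hr_samples) < min_hr_samples) return("too_few_hr")
  "valid"
}

#' Flag every main trial in a tidy trial table
#'
#' Vectorised counterpart of [flag_trial()] for one-row-per-trial tables
#' produced by [tidy_trials()].
#'
#' @param trials A tibble with `is_practice`, `delay_count` and
#'   `hr_sample_count` columns.
#' @param min_hr_samples See [flag_trial()].
#' @return The input with a `validity` column added.
#' @export
qc_flag_trials <- function(trials, min_hr_samples = 5) {
  if (any(trials$is_practice)) {
    stop("qc_flag_trials() expects practice trials to be removed first",
         call. = FALSE)
  }
  dplyr::mutate(
    trials,
    validity = dplyr::case_when(
      .data$delay_count == 0 ~ "zero_delays",
      .data$hr_sample_count < min_hr_samples ~ "too_few_hr",
      TRUE ~ "valid"
    )
  )
}

#' Select a participant's first K valid main trials
#'
#' Practice trials are removed, each main trial is flagged, and the first
#' `k` valid trials (in original order) are selected. Participants with
#' fewer than `min_valid_trials` valid trials in total are excluded; this is
#' a return state, not an error.
#'
#' @param session A [pat_session()].
#' @param k Number of trials to keep for scoring (default 17).
#' @param min_valid_trials Inclusion threshold on the total number of valid
#'   trials (default `k`).
#' @param min_hr_samples See [flag_trial()].
#' @return A list of class `pat_valid_trials`: `participant_id`, `trials`
#'   (list of the selected [pat_trial()]s), `selected_index` (their original
#'   main-trial positions), `validity_flags` (character vector over all main
#'   trials), `n_valid_total`, `n_main_trials`, `included` (logical).
#' @export
select_valid <- function(session, k = 17, min_valid_trials = k,
                         min_hr_samples = 5) {
  main <- purrr::keep(session$trials, ~ !.x$is_practice)
  flags <- vapply(main, flag_trial, character(1),
                  min_hr_samples = min_hr_samples)
  valid_idx <- which(flags == "valid")
  n_valid <- length(valid_idx)
  included <- n_valid >= min_valid_trials
  sel <- valid_idx[seq_len(min(k, n_valid))]
  structure(
    list(
      participant_id = session$participant_id,
      trials = main[sel],
      selected_index = sel,
      validity_flags = flags,
      n_valid_total = n_valid,
      n_main_trials = length(main),
      included = included
    ),
    class = "pat_valid_trials"
  )
}

#' Engagement summary over a participant's selected trials
#'
#' Aggregates the engagement metrics used for group matching: total and mean
#' time on trials, mean number of dial turns, and the total count of valid
#' trials.
#'
#' @param valid A `pat_valid_trials` object from [select_valid()].
#' @param count_unique_dial_positions Count only distinct dial positions per
#'   trial instead of the raw trace length (default `FALSE`).
#' @return A one-row tibble: `total_time_s`, `mean_time_per_trial_s`,
#'   `mean_dial_turns`, `n_valid_trials`.
#' @export
engagement_summary <- function(valid, count_unique_dial_positions = FALSE) {
  if (length(valid$trials) == 0) {
    stop("engagement_summary() needs at least one selected trial", call. = FALSE)
  }
  durations <- vapply(valid$trials, function(t) t$duration_s, numeric(1))
  turns <- vapply(valid$trials, function(t) {
    if (count_unique_dial_positions) length(unique(t$delay_trace))
    else length(t$delay_trace)
  }, numeric(1))
  tibble::tibble(
    total_time_s = sum(durations),
    mean_time_per_trial_s = mean(durations),
    mean_dial_turns = mean(turns),
    n_valid_trials = valid$n_valid_total
  )
}
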