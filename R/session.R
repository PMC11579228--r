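#' Construct a single PAT/screener trial record
#'
#' A trial holds everything the phase adjustment task records between the
#' trial-start tone and the confidence rating: the trace of dial-selected
#' delays (milliseconds), the confirmed final delay, heartbeat timestamps
#' within the trial, the instantaneous heart-rate samples logged alongside
#' them, the 0-9 confidence rating, and the trial duration.
#'
#' @param trial_index 1-based position of the trial in the session.
#' @param is_practice Logical; practice trials are never analysed.
#' @param delay_trace Numeric vector of dial-selected delays (ms), in the
#'   order they were set. May be empty when the participant never engaged
#'   the dial.
#' @param final_delay_ms The confirmed delay (ms). Must equal the last
#'   element of `delay_trace` when the trace is non-empty; `NA` allowed when
#'   the trace is empty.
#' @param beat_times_ms Strictly increasing heartbeat timestamps (ms from
#'   trial start).
#' @param hr_samples Instantaneous heart-rate values (beats/min) recorded
#'   during the trial.
#' @param confidence Integer 0-9, or `NA` when not given.
#' @param duration_s Trial duration in seconds (> 0).
#' @param body_map_location Optional free-text label of where the heartbeat
#'   was felt (stored, never analysed).
#' @return A list of class `pat_trial`.
#' @export
pat_trial <- function(trial_index, is_practice = FALSE, delay_trace = numeric(),
                      final_delay_ms = NA_real_, beat_times_ms = numeric(),
                      hr_samples = numeric(), confidence = NA_integer_,
                      duration_s = 1, body_map_location = NULL) {
  trial <- structure(
    list(
      trial_index = as.integer(trial_index),
      is_practice = isTRUE(is_practice),
      delay_trace = as.numeric(delay_trace),
      final_delay_ms = as.numeric(final_delay_ms),
      beat_times_ms = as.numeric(beat_times_ms),
      hr_samples = as.numeric(hr_samples),
      confidence = if (length(confidence) == 0 || is.na(confidence)) NA_integer_ else as.integer(confidence),
      duration_s = as.numeric(duration_s),
      body_map_location = body_map_location
    ),
    class = "pat_trial"
  )
  validate_pat_trial(trial)
  trial
}

validate_pat_trial <- function(trial) {
  if (length(trial$beat_times_ms) > 1 && any(diff(trial$beat_times_ms) <= 0)) {
    stop("trial ", trial$trial_index, ": beat_times_ms must be strictly increasing",
         call. = FALSE)
  }
  if (!is.na(trial$confidence) && (trial$confidence < 0 || trial$confidence > 9)) {
    stop("trial ", trial$trial_index, ": confidence must be in 0..9, got ",
         trial$confidence, call. = FALSE)
  }
  if (!is.na(trial$duration_s) && trial$duration_s <= 0) {
    stop("trial ", trial$trial_index, ": duration_s must be > 0", call. = FALSE)
  }
  if (length(trial$delay_trace) > 0) {
    last <- trial$delay_trace[length(trial$delay_trace)]
    if (is.na(trial$final_delay_ms) || abs(trial$final_delay_ms - last) > 1e-9) {
      stop("trial ", trial$trial_index,
           ": final_delay_ms must equal the last element of delay_trace",
           call. = FALSE)
    }
  }
  invisible(trial)
}

#' Construct a PAT or screener session
#'
#' A session is one participant's run of the phase adjustment task (or of the
#' structurally identical two-tone screener): a 2-minute baseline heartbeat
#' recording followed by two practice trials and nominally twenty main
#' trials.
#'
#' @param participant_id Opaque participant identifier.
#' @param task `"PAT"` or `"screener"`.
#' @param baseline_beats_ms Strictly increasing heartbeat timestamps (ms)
#'   covering the baseline window.
#' @param trials List of [pat_trial()] records, practice trials first.
#' @param dataset_id Study/dataset label (the pooled design uses 1-4).
#' @param baseline_duration_s Length of the baseline window in seconds
#'   (nominally 120).
#' @param metadata Named list of extra fields carried through I/O untouched.
#' @return A list of class `pat_session`.
#' @export
pat_session <- function(participant_id, task = c("PAT", "screener"),
                        baseline_beats_ms, trials, dataset_id = 1L,
                        baseline_duration_s = 120, metadata = list()) {
  task <- match.arg(task)
  session <- structure(
    list(
      schema = "pat-session/1",
      participant_id = as.character(participant_id),
      dataset_id = dataset_id,
      task = task,
      baseline_duration_s = as.numeric(baseline_duration_s),
      baseline_beats_ms = as.numeric(baseline_beats_ms),
      trials = trials,
      metadata = metadata
    ),
    class = "pat_session"
  )
  validate_pat_session(session)
  session
}

validate_pat_session <- function(session) {
  b <- session$baseline_beats_ms
  if (length(b) > 1 && any(diff(b) <= 0)) {
    stop("baseline_beats_ms must be strictly increasing (participant ",
         session$participant_id, ")", call. = FALSE)
  }
  practice <- vapply(session$trials, function(t) t$is_practice, logical(1))
  if (any(practice) && any(which(practice) > min(which(!practice), Inf))) {
    stop("practice trials must precede main trials (participant ",
         session$participant_id, ")", call. = FALSE)
  }
  for (t in session$trials) validate_pat_trial(t)
  invisible(session)
}

#' Number of main (non-practice) trials in a session
#' @param session A [pat_session()].
#' @return Integer count.
#' @export
n_main_trials <- function(session) {
  sum(!vapply(session$trials, function(t) t$is_practice, logical(1)))
}

#' @export
print.pat_session <- function(x, ...) {
  cat("<pat_session> participant", x$participant_id,
      "| task", x$task,
      "| dataset", as.character(x$dataset_id),
      "|", length(x$trials), "trials (", n_main_trials(x), "main )\n")
  invisible(x)
}

# --- JSON I/O ("pat-session/1" dialect) --------------------------------------

trial_to_list <- function(trial) {
  list(
    trial_index = trial$trial_index,
    is_practice = trial$is_practice,
    delay_trace = I(trial$delay_trace),
    final_delay_ms = trial$final_delay_ms,
    beat_times_ms = I(trial$beat_times_ms),
    hr_samples = I(trial$hr_samples),
    confidence = if (is.na(trial$confidence)) NULL else trial$confidence,
    duration_s = trial$duration_s,
    body_map_location = trial$body_map_location
  )
}

trial_from_list <- function(x, idx) {
  required <- c("trial_index", "is_practice", "delay_trace", "final_delay_ms",
                "beat_times_ms", "hr_samples", "duration_s")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("trial ", idx, ": missing field(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pat_trial(
    trial_index = x$trial_index,
    is_practice = x$is_practice,
    delay_trace = unlist(x$delay_trace) %||% numeric(),
    final_delay_ms = if (is.null(x$final_delay_ms)) NA_real_ else x$final_delay_ms,
    beat_times_ms = unlist(x$beat_times_ms) %||% numeric(),
    hr_samples = unlist(x$hr_samples) %||% numeric(),
    confidence = if (is.null(x$confidence)) NA_integer_ else x$confidence,
    duration_s = x$duration_s,
    body_map_location = x$body_map_location
  )
}

#' Read a session file in the "pat-session/1" JSON dialect
#'
#' The dialect stores one session per file with a fixed key order:
#' `schema`, `participant_id`, `dataset_id`, `task`, `baseline_duration_s`,
#' `baseline_beats_ms`, `trials`, `metadata`. Unknown top-level keys are not
#' an error; they are folded into the session's `metadata` so a rewrite
#' preserves them.
#'
#' @param path Path to a JSON file (or a connection jsonlite can read).
#' @return A validated [pat_session()].
#' @export
read_session <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$schema) || !identical(x$schema, "pat-session/1")) {
    stop("not a pat-session/1 file: schema field is ",
         if (is.null(x$schema)) "missing" else x$schema, call. = FALSE)
  }
  required <- c("participant_id", "task", "baseline_beats_ms", "trials")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("session file missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  known <- c("schema", "participant_id", "dataset_id", "task",
             "baseline_duration_s", "baseline_beats_ms", "trials", "metadata")
  extra <- x[setdiff(names(x), known)]
  metadata <- c(if (is.list(x$metadata)) x$metadata else list(), extra)
  trials <- purrr::imap(x$trials, trial_from_list)
  pat_session(
    participant_id = x$participant_id,
    task = x$task,
    baseline_beats_ms = unlist(x$baseline_beats_ms) %||% numeric(),
    trials = trials,
    dataset_id = x$dataset_id %||% NA,
    baseline_duration_s = x$baseline_duration_s %||% 120,
    metadata = metadata
  )
}

#' Write a session to the "pat-session/1" JSON dialect
#'
#' Key order is stable so that `write_session(read_session(p))` is
#' byte-normalised idempotent. Missing confidence serialises as an explicit
#' `null`.
#'
#' @param session A [pat_session()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_session <- function(session, path) {
  validate_pat_session(session)
  out <- list(
    schema = "pat-session/1",
    participant_id = session$participant_id,
    dataset_id = session$dataset_id,
    task = session$task,
    baseline_duration_s = session$baseline_duration_s,
    baseline_beats_ms = I(session$baseline_beats_ms),
    trials = purrr::map(session$trials, trial_to_list),
    metadata = session$metadata
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' Tidy a session into a one-row-per-trial table
#'
#' @param session A [pat_session()].
#' @return A tibble with one row per trial, in trial order: `participant_id`,
#'   `dataset_id`, `task`, `trial_index`, `is_practice`, `delay_count`,
#'   `final_delay_ms`, `hr_sample_count`, `n_beats`, `confidence`,
#'   `duration_s`.
#' @export
tidy_trials <- function(session) {
  validate_pat_session(session)
  purrr::map_dfr(session$trials, function(t) {
    tibble::tibble(
      participant_id = session$participant_id,
      dataset_id = as.character(session$dataset_id),
      task = session$task,
      trial_index = t$trial_index,
      is_practice = t$is_practice,
      delay_count = length(t$delay_trace),
      final_delay_ms = t$final_delay_ms,
      hr_sample_count = length(t$hr_samples),
      n_beats = length(t$beat_times_ms),
      confidence = t$confidence,
      duration_s = t$duration_s
    )
  })
}

#' Read a demographics table
#'
#' Expects a CSV with header `participant_id,sex,age_years,dataset_id`
#' (extra columns are kept). Sex must be one of `male`, `female`, `other`.
#'
#' @param path CSV path.
#' @return A tibble, one row per participant.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "sex", "age_years", "dataset_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("demographics file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !df$sex %in% c("male", "female", "other") & !is.na(df$sex)
  if (any(bad)) {
    stop("demographics: invalid sex value(s): ",
         paste(unique(df$sex[bad]), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
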