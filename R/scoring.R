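#' Phase angle of a selected delay on the cardiac cycle
#'
#' The confirmed delay is mapped onto the cardiac cycle by reducing it modulo
#' the inter-beat interval and rescaling the remainder to radians:
#' `2 * pi * ((delay mod ibi) / ibi)`, which lies in `[0, 2*pi)`.
#'
#' @param final_delay_ms Confirmed delay in ms (vectorised).
#' @param mean_ibi_ms Inter-beat interval in ms used as the cycle length
#'   (> 0).
#' @return Angle(s) in radians in `[0, 2*pi)`.
#' @export
trial_phase_angle <- function(final_delay_ms, mean_ibi_ms) {
  if (any(mean_ibi_ms <= 0)) {
    stop("mean_ibi_ms must be positive", call. = FALSE)
  }
  2 * pi * ((final_delay_ms %% mean_ibi_ms) / mean_ibi_ms)
}

#' Consistency of a set of phase angles
#'
#' Summarises how tightly a participant's selected tone-heartbeat phase
#' angles cluster across trials. The default method is the circular mean
#' resultant length `R = |sum(exp(i * theta))| / n`: 1 when all angles
#' coincide, near 0 when they are scattered uniformly around the dial. An
#' alternative pairwise angular-similarity score (mean over trial pairs of
#' `1 - d(theta_i, theta_j) / pi` with `d` the circular distance, rescaled
#' from its uniform-expectation of 1/2 onto `[0, 1]`) is available for
#' sensitivity analysis.
#'
#' @param angles_rad Numeric vector of at least 2 angles (radians).
#' @param method `"resultant_length"` (default) or `"pairwise_similarity"`.
#' @return A one-row tibble: `score` in `[0, 1]`, `n_trials`, `method`.
#' @export
consistency <- function(angles_rad,
                        method = c("resultant_length", "pairwise_similarity")) {
  method <- match.arg(method)
  tibble::tibble(score = consistency_score(angles_rad, method),
                 n_trials = length(angles_rad), method = method)
}

#' Bare consistency score
#'
#' Scalar core of [consistency()], returning just the score; useful inside
#' simulation loops.
#'
#' @inheritParams consistency
#' @return A single number in `[0, 1]`.
#' @export
consistency_score <- function(angles_rad,
                              method = c("resultant_length",
                                         "pairwise_similarity")) {
  method <- match.arg(method)
  n <- length(angles_rad)
  if (n < 2) stop("need at least 2 angles for a consistency score", call. = FALSE)
  switch(
    method,
    resultant_length = Mod(sum(exp(1i * angles_rad))) / n,
    pairwise_similarity = {
      d <- abs(outer(angles_rad, angles_rad, "-")) %% (2 * pi)
      d <- pmin(d, 2 * pi - d)
      sim <- mean(1 - d[upper.tri(d)] / pi)   # in [0, 1], 1/2 under uniformity
      max(0, 2 * sim - 1)
    }
  )
}

#' Score a session: selected delays -> phase angles -> consistency
#'
#' Applies QC ([select_valid()]), converts each selected trial's confirmed
#' delay to a phase angle using that trial's mean within-trial inter-beat
#' interval (or the baseline mean, by configuration), and reduces the angles
#' to the consistency score.
#'
#' @param session A [pat_session()].
#' @param k,min_valid_trials,min_hr_samples Passed to [select_valid()].
#' @param method Passed to [consistency()].
#' @param ibi_source `"trial"` (default; per-trial mean IBI from
#'   `beat_times_ms`) or `"baseline"` (session baseline mean IBI for every
#'   trial).
#' @return A one-row tibble: `participant_id`, `included`, `score`,
#'   `n_trials`, `method`, `n_valid_total`. `score` is `NA` when the
#'   participant is excluded by QC.
#' @export
score_session <- function(session, k = 17, min_valid_trials = k,
                          min_hr_samples = 5,
                          method = c("resultant_length", "pairwise_similarity"),
                          ibi_source = c("trial", "baseline")) {
  method <- match.arg(method)
  ibi_source <- match.arg(ibi_source)
  valid <- select_valid(session, k = k, min_valid_trials = min_valid_trials,
                        min_hr_samples = min_hr_samples)
  if (!valid$included) {
    return(tibble::tibble(
      participant_id = session$participant_id, included = FALSE,
      score = NA_real_, n_trials = length(valid$trials), method = method,
      n_valid_total = valid$n_valid_total
    ))
  }
  baseline_ibi <- mean(rr_from_beats(session$baseline_beats_ms))
  angles <- vapply(valid$trials, function(t) {
    ibi <- if (ibi_source == "trial" && length(t$beat_times_ms) >= 3) {
      mean(diff(t$beat_times_ms))
    } else {
      baseline_ibi
    }
    trial_phase_angle(t$final_delay_ms, ibi)
  }, numeric(1))
  res <- consistency(angles, method = method)
  tibble::tibble(
    participant_id = session$participant_id, included = TRUE,
    score = res$score, n_trials = res$n_trials, method = method,
    n_valid_total = valid$n_valid_total
  )
}

#' Screener pass rule
#'
#' The two-tone screener is passed when its consistency score strictly
#' exceeds the cut-off (default 0.42); a score exactly at the cut-off fails.
#'
#' @param score Consistency score(s) in `[0, 1]`.
#' @param threshold Pass cut-off (default 0.42).
#' @return Logical vector.
#' @export
screener_pass <- function(score, threshold = 0.42) {
  score > threshold
}
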