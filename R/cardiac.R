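#' RR intervals from baseline beat timestamps
#'
#' @param baseline_beats_ms Strictly increasing beat timestamps (ms); at
#'   least 3 beats are required for a usable series.
#' @return Numeric vector of successive inter-beat (RR) intervals in ms.
#' @export
rr_from_beats <- function(baseline_beats_ms) {
  if (length(baseline_beats_ms) < 3) {
    stop("need at least 3 baseline beats to form an RR series", call. = FALSE)
  }
  rr <- diff(baseline_beats_ms)
  if (any(rr <= 0)) {
    stop("baseline beat timestamps must be strictly increasing", call. = FALSE)
  }
  rr
}

#' Time-domain HRV summary of an RR series
#'
#' Standard time-domain definitions: resting heart rate is 60000 / mean(RR);
#' SDNN is the sample standard deviation (n-1 denominator) of the RR
#' intervals; RMSSD is the root-mean-square of successive RR differences;
#' pNN50 is the percentage of successive differences whose magnitude
#' strictly exceeds 50 ms, out of all successive pairs.
#'
#' @param rr Numeric vector of RR intervals in ms (>= 3 values).
#' @param rr_range Optional length-2 vector; when given, RR values outside
#'   the range are dropped before computing the metrics (artifact filter,
#'   off by default).
#' @return A one-row tibble: `resting_hr_bpm`, `sdnn_ms`, `rmssd_ms`,
#'   `pnn50_pct`, `n_rr`.
#' @export
hrv_summary <- function(rr, rr_range = NULL) {
  if (!is.null(rr_range)) {
    rr <- rr[rr >= rr_range[1] & rr <= rr_range[2]]
  }
  if (length(rr) < 3) {
    stop("need at least 3 RR intervals for HRV metrics", call. = FALSE)
  }
  d <- diff(rr)
  tibble::tibble(
    resting_hr_bpm = 60000 / mean(rr),
    sdnn_ms = stats::sd(rr),
    rmssd_ms = sqrt(mean(d^2)),
    pnn50_pct = 100 * mean(abs(d) > 50),
    n_rr = length(rr)
  )
}
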