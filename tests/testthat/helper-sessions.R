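# fixture builders used across the suite

make_trial <- function(index, is_practice = FALSE, n_delays = 12, n_hr = 20,
                       final = 400, ibi = 800, confidence = 5,
                       duration = 20) {
  trace <- if (n_delays > 0) c(seq_len(max(0, n_delays - 1)) * 10, final)
           else numeric()
  beats <- seq(0, by = ibi, length.out = max(n_hr + 1, 4))
  pat_trial(
    trial_index = index, is_practice = is_practice,
    delay_trace = trace,
    final_delay_ms = if (n_delays > 0) final else NA_real_,
    beat_times_ms = beats,
    hr_samples = rep(60000 / ibi, n_hr),
    confidence = confidence, duration_s = duration
  )
}

make_session <- function(id = "S1", n_practice = 2, n_main = 20,
                         invalid_main = integer(), invalid_kind = "zero_delays",
                         ibi = 800, task = "PAT", ...) {
  trials <- c(
    lapply(seq_len(n_practice), function(i) make_trial(i, TRUE, ibi = ibi, ...)),
    lapply(seq_len(n_main), function(i) {
      if (i %in% invalid_main) {
        if (invalid_kind == "zero_delays") {
          make_trial(n_practice + i, n_delays = 0, ibi = ibi, ...)
        } else {
          make_trial(n_practice + i, n_hr = 4, ibi = ibi, ...)
        }
      } else {
        make_trial(n_practice + i, ibi = ibi, ...)
      }
    })
  )
  pat_session(
    participant_id = id, task = task,
    baseline_beats_ms = seq(0, 120000, by = ibi),
    trials = trials
  )
}
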