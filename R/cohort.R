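#' Build the participant-level analysis table from raw sessions
#'
#' Runs the full ingest path: pick each participant's PAT session (first
#' completion with enough valid trials when duplicates exist), apply the
#' participant-level exclusions (missing demographics, extra trials from the
#' app fault, fewer than `min_valid_trials` valid trials), score the first
#' `k` valid trials, summarise confidence, engagement and baseline cardiac
#' metrics, score the screener where one was run, and attach mixture-based
#' classification labels fitted on the included cohort. Every dropped
#' participant is recorded with a reason in the exclusion ledger
#' (see [exclusion_ledger()]).
#'
#' @param sessions List of [pat_session()] objects (PAT and screener mixed).
#' @param demographics Tibble from [read_demographics()] (or equivalent).
#' @param k Trials scored per participant (default 17).
#' @param min_valid_trials Inclusion threshold on valid trials (default 17).
#' @param min_hr_samples Per-trial HR-sample floor (default 5).
#' @param max_main_trials Sessions with more main trials are excluded
#'   (default 20; the app fault added surplus trials).
#' @param method,ibi_source Passed to [score_session()].
#' @param belonging_method Passed to [belonging()].
#' @param em_seed Seed for the mixture fit (default 1).
#' @return A `pat_cohort` tibble, one row per included participant, with the
#'   exclusion ledger in `attr(, "exclusions")` and the full-cohort mixture
#'   fit in `attr(, "fit")`.
#' @export
build_cohort <- function(sessions, demographics, k = 17,
                         min_valid_trials = 17, min_hr_samples = 5,
                         max_main_trials = 20,
                         method = c("resultant_length", "pairwise_similarity"),
                         ibi_source = c("trial", "baseline"),
                         belonging_method = c("tail", "posterior"),
                         em_seed = 1) {
  method <- match.arg(method)
  ibi_source <- match.arg(ibi_source)
  belonging_method <- match.arg(belonging_method)

  task_of <- vapply(sessions, function(s) s$task, character(1))
  pat_sessions <- sessions[task_of == "PAT"]
  scr_sessions <- sessions[task_of == "screener"]
  pat_ids <- vapply(pat_sessions, function(s) s$participant_id, character(1))
  scr_ids <- vapply(scr_sessions, function(s) s$participant_id, character(1))

  exclusions <- list()
  rows <- list()

  for (id in unique(pat_ids)) {
    cand <- pat_sessions[pat_ids == id]
    session <- cand[[1]]
    if (length(cand) > 1) {
      # first available completion providing enough valid trials
      ok <- which(vapply(cand, function(s) {
        select_valid(s, k = k, min_valid_trials = min_valid_trials,
                     min_hr_samples = min_hr_samples)$included
      }, logical(1)))
      if (length(ok) > 0) session <- cand[[ok[1]]]
    }
    demo <- demographics[demographics$participant_id == id, ]
    exclude <- function(reason) {
      exclusions[[length(exclusions) + 1]] <<- tibble::tibble(
        participant_id = id, dataset_id = as.character(session$dataset_id),
        reason = reason)
    }
    if (nrow(demo) == 0 || is.na(demo$sex[1]) || is.na(demo$age_years[1])) {
      exclude("missing_demographics"); next
    }
    if (n_main_trials(session) > max_main_trials) {
      exclude("extra_trials"); next
    }
    valid <- select_valid(session, k = k, min_valid_trials = min_valid_trials,
                          min_hr_samples = min_hr_samples)
    if (!valid$included) {
      exclude("insufficient_valid_trials"); next
    }

    scored <- score_session(session, k = k,
                            min_valid_trials = min_valid_trials,
                            min_hr_samples = min_hr_samples,
                            method = method, ibi_source = ibi_source)
    conf <- vapply(valid$trials, function(t) as.numeric(t$confidence),
                   numeric(1))
    eng <- engagement_summary(valid)
    cardiac <- hrv_summary(rr_from_beats(session$baseline_beats_ms))

    scr_score <- NA_real_
    scr <- scr_sessions[scr_ids == id]
    if (length(scr) > 0) {
      s_res <- score_session(scr[[1]], k = k,
                             min_valid_trials = min_valid_trials,
                             min_hr_samples = min_hr_samples,
                             method = method, ibi_source = ibi_source)
      if (s_res$included) scr_score <- s_res$score
    }

    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(
        participant_id = id,
        dataset_id = as.character(session$dataset_id),
        sex = demo$sex[1],
        age_years = demo$age_years[1],
        consistency_score = scored$score,
        mean_confidence = if (all(is.na(conf))) NA_real_
                          else mean(conf, na.rm = TRUE),
        screener_score = scr_score,
        screener_pass = screener_pass(scr_score)
      ),
      eng, cardiac
    )
  }

  frame <- dplyr::bind_rows(rows)
  ledger <- if (length(exclusions) > 0) dplyr::bind_rows(exclusions) else
    tibble::tibble(participant_id = character(), dataset_id = character(),
                   reason = character())

  fit <- NULL
  if (nrow(frame) >= 20) {
    fit <- fit_gmm2(frame$consistency_score, seed = em_seed)
    cls <- classify(belonging(frame$consistency_score, fit,
                              method = belonging_method))
    frame$bayes_factor <- cls$bayes_factor
    frame$label_bf3 <- cls$label_bf3
    frame$label_bf10 <- cls$label_bf10
    frame$label_bf30 <- cls$label_bf30
  }

  structure(frame,
            exclusions = ledger, fit = fit,
            scoring = list(k = k, min_valid_trials = min_valid_trials,
                           min_hr_samples = min_hr_samples, method = method,
                           ibi_source = ibi_source,
                           belonging_method = belonging_method,
                           em_seed = em_seed),
            class = c("pat_cohort", class(frame)))
}

#' Exclusion ledger of a cohort frame
#' @param frame A cohort frame from [build_cohort()].
#' @return Tibble: `participant_id`, `dataset_id`, `reason`.
#' @export
exclusion_ledger <- function(frame) {
  attr(frame, "exclusions")
}

#' Declare an analysis sample as an ordered list of row predicates
#'
#' The pooled analysis reports four samples: the full cohort; the cohort
#' matched for engagement and demographics (at least 18 valid trials and no
#' 18-year-old females, the rule that removed the group differences in
#' engagement and age); the screener-passing subset (screener score > 0.42);
#' and the screened subset matched the same way. [pat_sample_specs()] ships
#' all four; the matching predicates are ordinary one-sided formulas and can
#' be replaced by the user.
#'
#' @param name Sample name.
#' @param predicates List of one-sided formulas evaluated in the frame
#'   (rows where a predicate is `NA` are dropped by that filter).
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(name, predicates = list()) {
  structure(list(name = name, predicates = predicates),
            class = "sample_spec")
}

#' The four shipped analysis-sample specifications
#' @return Named list of [sample_spec()] objects: `full`, `full_matched`,
#'   `screened`, `screened_matched`.
#' @export
pat_sample_specs <- function() {
  matched <- list(
    min_valid_18 = ~ n_valid_trials >= 18,
    no_female_18 = ~ !(sex == "female" & age_years == 18)
  )
  list(
    full = sample_spec("full"),
    full_matched = sample_spec("full_matched", matched),
    screened = sample_spec("screened", list(screener_passed = ~ screener_pass)),
    screened_matched = sample_spec(
      "screened_matched",
      c(list(screener_passed = ~ screener_pass), matched)
    )
  )
}

#' Apply a sample specification to a cohort frame
#'
#' @param frame A cohort frame.
#' @param spec A [sample_spec()].
#' @return The filtered frame, with per-filter attrition counts in
#'   `attr(, "attrition")`.
#' @export
apply_sample <- function(frame, spec) {
  attrition <- list()
  out <- frame
  for (nm in names(spec$predicates)) {
    f <- spec$predicates[[nm]]
    keep <- rlang::eval_tidy(rlang::f_rhs(f), data = out)
    keep <- !is.na(keep) & keep
    attrition[[length(attrition) + 1]] <- tibble::tibble(
      filter = nm, n_before = nrow(out), n_after = sum(keep))
    out <- out[keep, ]
  }
  if (nrow(out) == 0) warning("sample '", spec$name, "' is empty")
  attr(out, "attrition") <- if (length(attrition) > 0)
    dplyr::bind_rows(attrition) else
    tibble::tibble(filter = character(), n_before = integer(),
                   n_after = integer())
  attr(out, "sample_name") <- spec$name
  out
}

#' Run the full group-comparison report over the analysis samples
#'
#' For each sample: group descriptives; pooled t-tests on consistency and
#' mean confidence; a mixture refit on the sample's scores with
#' sex-by-classification tables and chi-squared tests at Bayes-factor
#' thresholds 3, 10 and 30; the nonparametric battery (rank-sum) over
#' engagement, cardiac metrics and age; pooled t-tests on consistency
#' residuals after regressing out resting HR and pNN50 (and additionally
#' age); and, where screener scores exist, the screener-vs-PAT Spearman
#' correlation.
#'
#' @param frame A cohort frame from [build_cohort()].
#' @param samples List of [sample_spec()]s (default [pat_sample_specs()]).
#' @param em_seed Seed for each per-sample mixture refit (default 1).
#' @param belonging_method Passed to [belonging()].
#' @return A `pat_report` list (serialisable with [write_report()]).
#' @export
run_report <- function(frame, samples = pat_sample_specs(), em_seed = 1,
                       belonging_method = c("tail", "posterior")) {
  belonging_method <- match.arg(belonging_method)
  sections <- purrr::map(samples, function(spec) {
    sub <- apply_sample(frame, spec)
    report_sample(sub, em_seed = em_seed,
                  belonging_method = belonging_method)
  })
  structure(
    list(
      schema = "pat-report/1",
      provenance = c(attr(frame, "scoring"),
                     list(report_em_seed = em_seed,
                          report_belonging_method = belonging_method,
                          n_cohort = nrow(frame))),
      exclusions = as.list(table(exclusion_ledger(frame)$reason)),
      samples = sections
    ),
    class = "pat_report"
  )
}

report_sample <- function(sub, em_seed, belonging_method) {
  out <- list(name = attr(sub, "sample_name"), n = nrow(sub))
  out$attrition <- attr(sub, "attrition")
  n_by_sex <- table(factor(sub$sex, levels = c("male", "female")))
  out$n_male <- unname(n_by_sex["male"])
  out$n_female <- unname(n_by_sex["female"])

  out$descriptives <- sub |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("consistency_score", "mean_confidence",
                      "total_time_s", "mean_time_per_trial_s",
                      "mean_dial_turns", "n_valid_trials",
                      "resting_hr_bpm", "sdnn_ms", "rmssd_ms", "pnn50_pct",
                      "age_years")),
      list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ stats::sd(.x, na.rm = TRUE))
    ), .groups = "drop")

  if (out$n_male < 2 || out$n_female < 2) {
    out$notice <- "fewer than 2 participants per sex: comparisons skipped"
    return(out)
  }

  out$consistency_t <- pooled_t_test(sub, .data$consistency_score, .data$sex)
  out$confidence_t <- pooled_t_test(sub, .data$mean_confidence, .data$sex)

  if (nrow(sub) >= 20 && stats::sd(sub$consistency_score) > 0) {
    fit <- fit_gmm2(sub$consistency_score, seed = em_seed)
    cls <- classify(belonging(sub$consistency_score, fit,
                              method = belonging_method))
    out$mixture <- tidy.pat_gmm(fit)
    out$classification <- purrr::map(c(3, 10, 30), function(lvl) {
      tab <- classification_table(cls[[paste0("label_bf", lvl)]], sub$sex)
      list(bf_level = lvl, table = tab, chisq = chisq_test(tab))
    })
  }

  battery_vars <- c("total_time_s", "mean_time_per_trial_s",
                    "mean_dial_turns", "n_valid_trials", "resting_hr_bpm",
                    "sdnn_ms", "rmssd_ms", "pnn50_pct", "age_years")
  out$rank_sum <- purrr::map_dfr(battery_vars, function(v) {
    dplyr::mutate(rank_sum_test(sub, .data[[v]], .data$sex), variable = v,
                  .before = 1)
  })

  res1 <- residualize(sub, consistency_score,
                      c("resting_hr_bpm", "pnn50_pct"))
  out$residual_t_hr_pnn50 <- pooled_t_test(res1, .data$.resid, .data$sex)
  res2 <- residualize(sub, consistency_score,
                      c("resting_hr_bpm", "pnn50_pct", "age_years"))
  out$residual_t_hr_pnn50_age <- pooled_t_test(res2, .data$.resid, .data$sex)

  with_scr <- sub[!is.na(sub$screener_score), ]
  if (nrow(with_scr) >= 3 && stats::sd(with_scr$screener_score) > 0) {
    out$screener_spearman <- spearman_test(with_scr, .data$screener_score,
                                           .data$consistency_score)
  }
  out
}

#' Serialise a report to deterministic JSON ("pat-report/1")
#'
#' Given identical inputs, configuration and seed, the written file is
#' byte-identical.
#'
#' @param report A `pat_report` from [run_report()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "rows", pretty = TRUE)
  invisible(path)
}
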