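#' Simulation configuration for synthetic PAT cohorts
#'
#' Defaults describe a pooled smartphone cohort: 266 participants with the
#' study's sex split; a two-subpopulation structure in selected phase delays
#' (interoceptive participants draw trial angles from a von Mises around a
#' personal preferred phase, non-interoceptive participants draw uniform
#' angles); AR(1) RR-interval dynamics around a participant-level mean IBI;
#' ordinal 0-9 confidence from a latent normal with a male-positive shift;
#' Poisson dial-turn counts and lognormal trial durations; and injected
#' quality-control failures (empty dial traces, sparse heart-rate logs,
#' extra trials, missing demographics).
#'
#' @param n_participants Cohort size (default 266).
#' @param p_female Probability a participant is female (default 163/266).
#' @param age_min,age_max,age_shape,age_scale Age model: `age_min` plus a
#'   gamma(shape, scale) draw, truncated at `age_max`.
#' @param p_interoceptive Named vector: probability of being truly
#'   interoceptive, by sex (default `c(male = 0.35, female = 0.55)`).
#' @param kappa_interoceptive von Mises concentration of interoceptive
#'   participants' trial angles (default 1.5).
#' @param mean_ibi_mean,mean_ibi_sd Across-participant law of the mean
#'   inter-beat interval, ms (default 780, 90).
#' @param ibi_sex_shift_ms Added to male mean IBI and subtracted from female
#'   (females rest at slightly higher heart rate; default 15 ms).
#' @param rr_phi AR(1) coefficient of within-participant RR dynamics
#'   (default 0.35).
#' @param rr_innov_sd Named vector of AR(1) innovation SDs (ms) by sex
#'   (default `c(male = 52, female = 58)`; the female excess yields the
#'   higher pNN50 typical of such cohorts).
#' @param confidence_mean Named vector of latent confidence means by sex
#'   (default `c(male = 5.5, female = 4.6)`).
#' @param confidence_sd Latent confidence SD (default 2).
#' @param dial_turns_mean Poisson mean of dial positions per trial
#'   (default 26).
#' @param duration_meanlog,duration_sdlog Lognormal trial-duration
#'   parameters, seconds (default `log(20)`, 0.45).
#' @param n_practice,n_main Trial counts (default 2, 20).
#' @param baseline_duration_s Baseline window (default 120 s).
#' @param p_empty_trace,p_sparse_hr Per-main-trial injection rates of the
#'   two QC failure modes (defaults 0.015 each).
#' @param p_extra_trials Per-participant rate of the extra-trials technical
#'   fault (two surplus main trials; default 0.01).
#' @param p_missing_demographics Per-participant rate of a missing
#'   demographics row (default 0.01).
#' @param dataset_probs Probabilities of dataset membership 1-4
#'   (default proportional to 86/116/54/10).
#' @param p_screener_ds2 Probability a dataset-2 participant completed the
#'   screener (dataset 1 always did; default 0.9).
#' @param screener_kappa_meanlog,screener_kappa_sdlog Lognormal law of the
#'   per-participant screener matching skill (a von Mises concentration;
#'   defaults `log(6)`, 0.6).
#' @param sex_effect Logical; when `FALSE` every sex-linked parameter
#'   (interoceptive proportion, confidence shift, IBI shift, innovation SD)
#'   is replaced by its across-sex average, giving a null cohort.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 266,
                       p_female = 163 / 266,
                       age_min = 18, age_max = 60,
                       age_shape = 1.5, age_scale = 6.5,
                       p_interoceptive = c(male = 0.35, female = 0.55),
                       kappa_interoceptive = 1.5,
                       mean_ibi_mean = 780, mean_ibi_sd = 90,
                       ibi_sex_shift_ms = 15,
                       rr_phi = 0.35,
                       rr_innov_sd = c(male = 52, female = 58),
                       confidence_mean = c(male = 5.5, female = 4.6),
                       confidence_sd = 2,
                       dial_turns_mean = 26,
                       duration_meanlog = log(20), duration_sdlog = 0.45,
                       n_practice = 2, n_main = 20,
                       baseline_duration_s = 120,
                       p_empty_trace = 0.015, p_sparse_hr = 0.015,
                       p_extra_trials = 0.01,
                       p_missing_demographics = 0.01,
                       dataset_probs = c(86, 116, 54, 10) / 266,
                       p_screener_ds2 = 0.9,
                       screener_kappa_meanlog = log(6),
                       screener_kappa_sdlog = 0.6,
                       sex_effect = TRUE) {
  cfg <- as.list(environment())
  if (!sex_effect) {
    cfg$p_interoceptive[] <- mean(p_interoceptive)
    cfg$confidence_mean[] <- mean(confidence_mean)
    cfg$ibi_sex_shift_ms <- 0
    cfg$rr_innov_sd[] <- mean(rr_innov_sd)
  }
  stopifnot(cfg$p_female >= 0, cfg$p_female <= 1,
            all(cfg$p_interoceptive >= 0), all(cfg$p_interoceptive <= 1),
            cfg$kappa_interoceptive >= 0)
  structure(cfg, class = "sim_config")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the circular
#' uniform.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    out <- c(out, theta)
  }
  (out[seq_len(n)] + mu) %% (2 * pi)
}

# AR(1) RR sequence (ms) of length n around mean_ibi; floors at 300 ms
sim_rr <- function(n, mean_ibi, phi, innov_sd) {
  e <- stats::rnorm(n, 0, innov_sd)
  rr <- numeric(n)
  prev <- 0
  for (i in seq_len(n)) {
    prev <- phi * prev + e[i]
    rr[i] <- mean_ibi + prev
  }
  pmax(rr, 300)
}

sim_beats <- function(window_ms, mean_ibi, phi, innov_sd) {
  n <- ceiling(window_ms / mean_ibi * 1.4) + 8
  rr <- sim_rr(n, mean_ibi, phi, innov_sd)
  beats <- cumsum(c(0, rr))
  beats[beats <= window_ms]
}

sim_trial <- function(idx, is_practice, cfg, person, task) {
  duration_s <- stats::rlnorm(1, cfg$duration_meanlog, cfg$duration_sdlog)
  beats <- sim_beats(duration_s * 1000, person$mean_ibi, cfg$rr_phi,
                     person$innov_sd)
  while (length(beats) < 6) {   # very short draw: extend so IBI is defined
    duration_s <- duration_s * 1.5
    beats <- sim_beats(duration_s * 1000, person$mean_ibi, cfg$rr_phi,
                       person$innov_sd)
  }
  ibi <- mean(diff(beats))
  theta <- if (task == "screener") {
    rvonmises(1, person$screener_phase, person$screener_kappa)
  } else if (person$status == "interoceptive") {
    rvonmises(1, person$preferred_phase, cfg$kappa_interoceptive)
  } else {
    stats::runif(1, 0, 2 * pi)
  }
  final_delay <- round(theta / (2 * pi) * ibi)
  n_turns <- stats::rpois(1, cfg$dial_turns_mean) + 1
  trace <- c(round(stats::runif(n_turns - 1, 0, ibi)), final_delay)
  conf <- round(stats::rnorm(1, person$confidence_mu, cfg$confidence_sd))
  pat_trial(
    trial_index = idx, is_practice = is_practice,
    delay_trace = trace, final_delay_ms = final_delay,
    beat_times_ms = round(beats, 1),
    hr_samples = round(60000 / diff(beats), 1),
    confidence = min(9L, max(0L, as.integer(conf))),
    duration_s = round(duration_s, 2)
  )
}

#' Generate a complete synthetic cohort
#'
#' Produces one PAT session per participant (plus a screener session for
#' datasets that ran it), a demographics table, and a ground-truth table
#' recording each participant's true status and every injected QC failure,
#' so downstream exclusion accounting can be checked exactly.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; the whole cohort is reproducible from
#'   it.
#' @return A list: `sessions` (list of [pat_session()], PAT and screener),
#'   `demographics` (tibble; participants with the injected
#'   missing-demographics fault are absent), `ground_truth` (tibble).
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n <- cfg$n_participants
  sex <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")
  age <- pmin(cfg$age_max,
              cfg$age_min + round(stats::rgamma(n, cfg$age_shape, scale = cfg$age_scale)))
  dataset <- sample(seq_along(cfg$dataset_probs), n, replace = TRUE,
                    prob = cfg$dataset_probs)
  status <- ifelse(stats::runif(n) < cfg$p_interoceptive[sex],
                   "interoceptive", "non_interoceptive")
  pref <- stats::runif(n, 0, 2 * pi)
  ibi_shift <- ifelse(sex == "male", cfg$ibi_sex_shift_ms, -cfg$ibi_sex_shift_ms)
  mean_ibi <- pmin(1200, pmax(500, stats::rnorm(n, cfg$mean_ibi_mean + ibi_shift,
                                                cfg$mean_ibi_sd)))
  has_screener <- dataset == 1 |
    (dataset == 2 & stats::runif(n) < cfg$p_screener_ds2)
  screener_kappa <- ifelse(has_screener,
                           stats::rlnorm(n, cfg$screener_kappa_meanlog,
                                         cfg$screener_kappa_sdlog), NA_real_)
  screener_phase <- stats::runif(n, 0, 2 * pi)
  extra_trials <- stats::runif(n) < cfg$p_extra_trials
  missing_demo <- stats::runif(n) < cfg$p_missing_demographics

  ids <- sprintf("P%04d", seq_len(n))
  sessions <- vector("list", 0)
  gt_rows <- vector("list", n)

  for (i in seq_len(n)) {
    person <- list(
      status = status[i], preferred_phase = pref[i], mean_ibi = mean_ibi[i],
      innov_sd = unname(cfg$rr_innov_sd[sex[i]]),
      confidence_mu = unname(cfg$confidence_mean[sex[i]]),
      screener_phase = screener_phase[i], screener_kappa = screener_kappa[i]
    )
    n_main <- cfg$n_main + if (extra_trials[i]) 2 else 0
    trials <- vector("list", cfg$n_practice + n_main)
    for (j in seq_len(cfg$n_practice)) {
      trials[[j]] <- sim_trial(j, TRUE, cfg, person, "PAT")
    }
    n_empty <- 0L; n_sparse <- 0L
    for (j in seq_len(n_main)) {
      t <- sim_trial(cfg$n_practice + j, FALSE, cfg, person, "PAT")
      u <- stats::runif(1)
      if (u < cfg$p_empty_trace) {
        t$delay_trace <- numeric()
        t$final_delay_ms <- NA_real_
        n_empty <- n_empty + 1L
      } else if (u < cfg$p_empty_trace + cfg$p_sparse_hr) {
        t$hr_samples <- t$hr_samples[seq_len(min(4, length(t$hr_samples)))]
        n_sparse <- n_sparse + 1L
      }
      trials[[cfg$n_practice + j]] <- t
    }
    baseline <- sim_beats(cfg$baseline_duration_s * 1000, person$mean_ibi,
                          cfg$rr_phi, person$innov_sd)
    sessions[[length(sessions) + 1]] <- pat_session(
      participant_id = ids[i], task = "PAT",
      baseline_beats_ms = round(baseline, 1), trials = trials,
      dataset_id = dataset[i],
      baseline_duration_s = cfg$baseline_duration_s
    )
    if (has_screener[i]) {
      s_trials <- vector("list", cfg$n_practice + cfg$n_main)
      for (j in seq_len(cfg$n_practice + cfg$n_main)) {
        s_trials[[j]] <- sim_trial(j, j <= cfg$n_practice, cfg, person,
                                   "screener")
      }
      s_baseline <- sim_beats(cfg$baseline_duration_s * 1000, person$mean_ibi,
                              cfg$rr_phi, person$innov_sd)
      sessions[[length(sessions) + 1]] <- pat_session(
        participant_id = ids[i], task = "screener",
        baseline_beats_ms = round(s_baseline, 1), trials = s_trials,
        dataset_id = dataset[i],
        baseline_duration_s = cfg$baseline_duration_s
      )
    }
    gt_rows[[i]] <- tibble::tibble(
      participant_id = ids[i], sex = sex[i], age_years = age[i],
      dataset_id = dataset[i], status = status[i],
      preferred_phase = pref[i], mean_ibi_ms = mean_ibi[i],
      kappa = ifelse(status[i] == "interoceptive",
                     cfg$kappa_interoceptive, 0),
      has_screener = has_screener[i], screener_kappa = screener_kappa[i],
      n_empty_trace = n_empty, n_sparse_hr = n_sparse,
      extra_trials = extra_trials[i],
      missing_demographics = missing_demo[i]
    )
  }

  ground_truth <- dplyr::bind_rows(gt_rows)
  demographics <- ground_truth |>
    dplyr::filter(!.data$missing_demographics) |>
    dplyr::select("participant_id", "sex", "age_years", "dataset_id")
  list(sessions = sessions, demographics = demographics,
       ground_truth = ground_truth)
}

#' Fast score-level cohort: per-participant phase angles and consistency
#'
#' Skips session plumbing and draws each participant's `k` final phase
#' angles directly (von Mises for interoceptive participants, uniform
#' otherwise), scoring them with the same consistency statistic the full
#' pipeline uses. Intended for calibration studies that need many
#' replicates of the score-by-sex comparison.
#'
#' @param n Cohort size.
#' @param p_female Probability female.
#' @param p_interoceptive Named per-sex probability of true interoceptive
#'   status.
#' @param kappa von Mises concentration for interoceptive participants.
#' @param k Trials per participant (default 17).
#' @return Tibble: `participant_id`, `sex`, `status`, `score`.
#' @export
simulate_angle_cohort <- function(n = 266, p_female = 163 / 266,
                                  p_interoceptive = c(male = 0.35,
                                                      female = 0.55),
                                  kappa = 1.5, k = 17) {
  sex <- ifelse(stats::runif(n) < p_female, "female", "male")
  status <- ifelse(stats::runif(n) < p_interoceptive[sex],
                   "interoceptive", "non_interoceptive")
  n_int <- sum(status == "interoceptive")
  angles <- matrix(stats::runif(n * k, 0, 2 * pi), nrow = n)
  if (n_int > 0) {
    pref <- stats::runif(n_int, 0, 2 * pi)
    angles[status == "interoceptive", ] <-
      matrix(rvonmises(n_int * k, 0, kappa), nrow = n_int) + pref
  }
  score <- vapply(seq_len(n),
                  function(i) consistency_score(angles[i, ] %% (2 * pi)),
                  numeric(1))
  tibble::tibble(participant_id = sprintf("P%04d", seq_len(n)),
                 sex = sex, status = status, score = score)
}

#' Draw scores from a two-component Gaussian mixture
#'
#' Score-level generator matching the structure the mixture classifier
#' assumes; used for parameter-recovery checks where the true component
#' means must be known exactly.
#'
#' @param n Number of scores.
#' @param weights,means,sds Component parameters, low-scoring component
#'   first (defaults `c(0.55, 0.45)`, `c(0.22, 0.55)`, `c(0.07, 0.12)`).
#' @return Numeric vector of scores.
#' @export
simulate_scores <- function(n, weights = c(0.55, 0.45),
                            means = c(0.22, 0.55), sds = c(0.07, 0.12)) {
  comp <- 1 + (stats::runif(n) < weights[2])
  stats::rnorm(n, means[comp], sds[comp])
}

#' Recovery metrics: classifications against simulated ground truth
#'
#' @param ground_truth Tibble with `participant_id` and true `status`.
#' @param classified Tibble with `participant_id` and `label_bf3`,
#'   `label_bf10`, `label_bf30` columns (e.g. a cohort frame).
#' @return Tibble with one row per BF level: `bf_level`, `sensitivity`
#'   (truly interoceptive labelled interoceptive), `specificity` (truly
#'   non-interoceptive not labelled interoceptive), `n_true_interoceptive`,
#'   `n_true_non_interoceptive`.
#' @export
truth_report <- function(ground_truth, classified) {
  joined <- dplyr::inner_join(
    dplyr::select(ground_truth, "participant_id", "status"),
    classified, by = "participant_id"
  )
  if (nrow(joined) == 0) stop("no matching participant ids", call. = FALSE)
  purrr::map_dfr(c(3, 10, 30), function(lvl) {
    lab <- joined[[paste0("label_bf", lvl)]]
    true_int <- joined$status == "interoceptive"
    tibble::tibble(
      bf_level = lvl,
      sensitivity = if (any(true_int))
        mean(lab[true_int] == "interoceptive") else NA_real_,
      specificity = if (any(!true_int))
        mean(lab[!true_int] != "interoceptive") else NA_real_,
      n_true_interoceptive = sum(true_int),
      n_true_non_interoceptive = sum(!true_int)
    )
  })
}
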