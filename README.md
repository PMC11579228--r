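# phasetask

Analysis pipeline for the **Phase Adjustment Task (PAT)**, a smartphone
measure of cardiac interoceptive accuracy. In the PAT, tones are triggered by
the participant's own heartbeat but presented out of phase, and the
participant turns a virtual dial to advance or delay the tones until they
feel synchronous. Because the starting phase is random on every trial,
*accuracy is inferred from consistency*: a participant who reliably selects
the same tone–heartbeat phase relationship across trials can perceive their
heartbeat; one whose selected delays scatter randomly around the cardiac
cycle cannot. The package is aimed at psychophysiology researchers who need
a reproducible, testable route from raw PAT session files to the
participant-level statistics usually reported for this task.

## What it computes

Each selected delay is mapped onto the cardiac cycle as a phase angle
θ = 2π·((delay mod IBI)/IBI), where IBI is the mean inter-beat interval, and
a participant's K = 17 scored trials are reduced to the **consistency
score**, the circular mean resultant length

    R = | Σ exp(i·θ_j) | / K  ∈ [0, 1],

which is 1 when all angles coincide and near 0 under uniform scatter
(E[R] = √π / (2√K) ≈ 0.215 at K = 17 under the null).

Cohort scores are modelled as a **two-component Gaussian mixture** fitted by
expectation–maximisation; the higher-mean component is the interoceptive
one. Each participant gets component z-scores z_k = (R − μ_k)/σ_k, two-sided
normal-tail belonging probabilities p_k = P(|Z| ≥ |z_k|), and a **Bayes
factor** BF = max(p)/min(p). Labels (interoceptive / non-interoceptive /
unclassified) are assigned at evidence thresholds BF > 3, > 10 and > 30.

Around that core the package provides:

* a documented JSON session dialect (`pat-session/1`) with validating
  reader/writer and a tidy one-row-per-trial export;
* trial quality control (trials with an empty dial trace or ≤ 4 heart-rate
  samples are dropped; participants with < 17 valid main trials are
  excluded) and engagement metrics;
* RR-interval extraction from the 2-minute baseline with time-domain HRV
  (SDNN, RMSSD, pNN50) and resting heart rate;
* the group-comparison battery: pooled t-test, Pearson χ² with empty-category
  dropping and no continuity correction, tie-corrected Mann–Whitney Z,
  Spearman rank correlation, OLS residualization, one-way ANOVA, and
  analytic two-sample power via the noncentral t;
* an end-to-end cohort pipeline with exact exclusion accounting and a
  deterministic JSON report over the four standard analysis samples;
* a synthetic-cohort generator (sessions, demographics, ground truth) so the
  entire pipeline is testable without participant data.

## Worked example

```r
library(phasetask)

sim   <- simulate_cohort(sim_config(n_participants = 120), seed = 42)
frame <- build_cohort(sim$sessions, sim$demographics)

nrow(frame)
#> [1] 115
dplyr::count(exclusion_ledger(frame), reason)
#>   reason                        n
#> 1 extra_trials                  3
#> 2 insufficient_valid_trials     1
#> 3 missing_demographics          1

attr(frame, "fit")
#> <pat_gmm> two-component Gaussian mixture (EM), n = 115
#>   non_interoceptive w = 0.476, mean = 0.1768, sd = 0.0777
#>   interoceptive     w = 0.524, mean = 0.5831, sd = 0.1448
#>   logLik = 25.0636 after 86 iterations (converged)

pooled_t_test(frame, consistency_score, sex)[, c("statistic", "df", "p_value")]
#>   statistic  df   p_value
#> 1 -1.136744 113 0.2580503

tab <- classification_table(frame$label_bf30, frame$sex)
tab
#>   sex    non_interoceptive unclassified interoceptive
#> 1 male                  24            8            21
#> 2 female                19           11            32
chisq_test(tab)
#>   test          statistic df p_value   n
#> 1 pearson_chisq      2.65  2   0.266 115
```

The five excluded participants match the generator's injected faults
exactly; the fitted component means (0.18 / 0.58) recover the
two-subpopulation structure the generator plants (uniform angles vs. von
Mises-concentrated angles); and at this cohort size the sex difference in
mean consistency is not significant — with 120 participants the comparison
is underpowered relative to the injected effect, as `power_two_sample()`
will confirm. `run_report(frame)` assembles the same quantities, per
analysis sample, into a deterministic JSON report;
`truth_report(sim$ground_truth, frame)` scores classification recovery
against the generator's ground truth.

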