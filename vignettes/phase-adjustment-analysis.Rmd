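---
title: "Scoring and classifying phase adjustment task data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying phase adjustment task data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasetask)
```

## The measurement model

The phase adjustment task presents tones triggered by the participant's own
heartbeat but shifted by a delay, and asks the participant to adjust that
delay until tones and heartbeats feel simultaneous. The starting delay is
randomised per trial, so nothing about heart-rate knowledge helps: the only
way to respond consistently is to perceive the heartbeat. The analysis
therefore treats the *confirmed delay* of each trial as the datum, maps it
onto the cardiac cycle as a phase angle

$$\theta_j = 2\pi\,\frac{d_j \bmod \overline{\mathrm{IBI}}_j}{\overline{\mathrm{IBI}}_j},$$

and summarises a participant's $K$ angles by the circular mean resultant
length $R = |\sum_j e^{i\theta_j}|/K$. $R$ is 1 when all angles coincide and
has expectation $\sqrt{\pi}/(2\sqrt{K}) \approx 0.215$ at $K = 17$ under
uniform scatter; it is invariant to rotation (a constant perceptual delay
does not penalise the score) and to trial order.

Two modelling choices here were genuinely open and are exposed as
configuration rather than hard-coded:

* **Cycle length per trial.** Tones are heartbeat-triggered, so the natural
  cycle is the trial's own mean inter-beat interval (`ibi_source = "trial"`,
  the default). Using the baseline mean IBI for every trial
  (`"baseline"`) is available for sensitivity analysis; the two differ only
  through within-session heart-rate drift.
* **The consistency statistic.** The mean resultant length is the canonical
  circular-concentration statistic with exactly the advertised behaviour
  (1 when aligned, near 0 when random). A pairwise angular-similarity
  alternative — the mean over trial pairs of $1 - d(\theta_i,\theta_j)/\pi$,
  rescaled from its uniform expectation of $1/2$ onto $[0,1]$ — is provided
  (`method = "pairwise_similarity"`) because task software in this area has
  described its score in pairwise terms without publishing the formula.
  All shipped defaults and all tests use the resultant length, and every
  result records which method produced it. A consequence worth flagging in
  reports: whether the screener pass rule's 0.42 cut-off lies on the same
  numeric scale as the resultant length cannot be confirmed from public
  sources; the package applies it to the resultant-length score.

Only the confirmed final delay enters scoring. The dial-adjustment trace
feeds engagement metrics alone, on the view that intermediate dial positions
are exploration, not judgements.

## Quality control

Practice trials (the first two) are removed. A main trial is *valid* when
the participant actually engaged the dial (non-empty delay trace) and the
app logged at least five heart-rate values; trials failing either check are
dropped as non-engagement. Participants with fewer than 17 valid main trials
(of nominally 20) are excluded, and exactly the first 17 valid trials are
scored so every included participant contributes the same trial count.
Sessions with more than 20 main trials (an app fault) are excluded outright,
as are participants without sex or age. When a participant has multiple
completions, the first one providing 17 valid trials is used. Every
exclusion is written to a ledger with its reason; the pipeline's accounting
identity (recruited = included + excluded, per reason) is asserted in the
test suite against the generator's injected fault counts.

The QC thresholds are configuration (`k`, `min_valid_trials`,
`min_hr_samples`): the engagement-matched analyses, for example, raise the
inclusion threshold to 18 valid trials while still scoring 17. "At least 17
valid trials" is interpreted as a total count over the 20 main trials, not a
count within the first N.

## Cardiac metrics

RR intervals are the successive differences of the 2-minute baseline beat
timestamps. Resting heart rate is $60000/\overline{RR}$ bpm. SDNN uses the
sample (n−1) standard deviation; RMSSD is the root-mean-square of successive
differences; pNN50 is the percentage of successive differences strictly
exceeding 50 ms, with the number of successive pairs as denominator. These
are the standard time-domain conventions; where published tables do not
state the variant, the standard one is used. No artifact or ectopic-beat
correction is applied by default — an optional RR-range filter
(`rr_range`) exists but is off, since no preprocessing of that kind is
documented for this task's published analyses.

## Mixture classification

Cohort consistency scores are modelled as a two-component univariate
Gaussian mixture fitted by EM. Numerical choices:

* **Initialisation:** first restart from the 25th/75th percentiles with
  equal weights and σ = half the pooled SD; nine further seeded random
  restarts (means sampled from the data, weights in [0.3, 0.7]); best
  log-likelihood kept. With a fixed `seed` the fit is bit-reproducible, and
  the RNG state of the caller is left untouched.
* **Convergence:** absolute log-likelihood change < 1e-8, at most 1000
  iterations; the E-step works in log space with log-sum-exp.
* **Variance floor:** σ ≥ 1e-3, preventing a component from collapsing onto
  a single score on this bounded scale.
* **Labelling:** the higher-mean component is "interoceptive", since higher
  consistency means better perception. Ties cannot survive the variance
  floor plus distinct initial means in practice; mirrored data mirror the
  fit and swap labels (asserted in tests).

Each participant's score then receives a z-score under each component and a
*belonging probability*. The default follows the z-score route: the
two-sided normal tail $p_k = P(|Z| \ge |z_k|)$, so a score at a component
mean belongs to it with probability 1 regardless of mixture weights. The
posterior alternative (`belonging(..., method = "posterior")`) weights
component densities and normalises. Both are implemented because published
descriptions derive probabilities "from z-scores" without stating whether
weights entered; the tail method is the default precisely because it is the
literal z-score reading, and every output records the method. The Bayes
factor is the larger belonging probability over the smaller (≥ 1 by
construction, probabilities floored at 1e-300 before the ratio), and labels
use strict inequalities at 3, 10 and 30, which makes the three labellings
nested.

The mixture is refit within each analysis sample by default — a
classification should be relative to the cohort actually analysed — with the
full-cohort fit also attached to the frame for users who prefer to freeze
one fit.

## The statistics battery

* Pooled-variance Student t (df = n₁ + n₂ − 2), two-tailed — the df printed
  for this task's published consistency comparisons identify the pooled
  form.
* Pearson χ² with **no continuity correction** and **all-zero rows/columns
  dropped** before computing; at the strictest evidence threshold nobody is
  labelled non-interoceptive, and the published statistics are only
  reproducible on the reduced table (df = 1). Both choices are verified to
  three decimals against twelve published tables in the acceptance suite.
* Mann–Whitney rank-sum with mid-ranks, tie-corrected normal approximation,
  no continuity correction by default (a flag enables it); |Z| is reported
  because the published engagement/heart-rate tables print non-negative Z,
  and the signed value is kept alongside.
* Spearman correlation as Pearson on mid-ranks with the t-approximation
  p-value.
* Residualization as OLS with intercept; group tests on residuals keep
  df = n − 2, matching the published residual t-tests.
* One-way ANOVA from the usual sums-of-squares decomposition.
* Two-sample power through the noncentral t with
  ncp = d·√(n₁n₂/(n₁+n₂)), supporting unequal groups.

No multiple-testing correction is applied anywhere, mirroring the analysis
this package reimplements; p-values are raw and two-tailed.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without
participant data. It emulates the statistical structure the analysis
assumes, with defaults fixed once:

| Parameter | Default | Rationale |
|---|---|---|
| n_participants | 266 | pooled cohort size |
| p_female | 163/266 | pooled sex split |
| p_interoceptive | male 0.35, female 0.55 | status-channel sex effect |
| kappa_interoceptive | 1.5 | places the upper score component near 0.55, since E[R] = I₁(κ)/I₀(κ) ≈ 0.57 |
| mean IBI | Normal(780, 90) ms, ±15 ms by sex | resting HR in the 70s bpm, females slightly higher |
| RR dynamics | AR(1), φ = 0.35, innovation SD 52 (m) / 58 (f) ms | SDNN near 60 ms and pNN50 in the 40s, female-higher, plausible for 2-minute optical recordings |
| confidence | latent Normal, mean 5.5 (m) / 4.6 (f), SD 2, rounded and clamped to 0–9 | male-positive confidence shift of the published direction and size |
| engagement | dial turns Poisson(26)+1; durations lognormal(log 20, 0.45) s | ~20 s trials, ~26 dial positions |
| QC faults | 1.5% empty-trace and 1.5% sparse-HR per trial; 1% extra-trials; 1% missing demographics | retains the large majority of participants, as observed attrition does |
| screener | datasets 1 and 2 (90%); matching skill κ ~ lognormal(log 6, 0.6) | high pass rates on a two-tone matching control |

Non-interoceptive participants draw trial angles uniformly; interoceptive
participants draw von Mises angles around a personal preferred phase. The
sex effect is injected through the *proportion* of interoceptive
participants rather than through κ because group comparisons of the score
cannot distinguish the two mechanisms; a κ channel remains available by
configuration. `sex_effect = FALSE` collapses every sex-linked parameter to
its average, giving a null cohort for calibration studies.

Two deliberate simplifications: `simulate_angle_cohort()` draws per-
participant angles directly and scores them with the same consistency
statistic, skipping session plumbing — calibration suites that need
thousands of replicates of the score-by-sex comparison use it; and
`simulate_scores()` draws from the two-component Gaussian itself
(weights 0.55/0.45, means 0.22/0.55, SDs 0.07/0.12) for parameter-recovery
checks, where the true component means must be known exactly.

What the generator does **not** emulate: photoplethysmography noise and beat
detection errors, pulse-transit-time offsets between the heartbeat and its
perceptible pulse, within-participant learning or fatigue across trials,
circadian or postural heart-rate structure beyond AR(1), and any correlation
between confidence and accuracy. Passing tests therefore demonstrate that
the *pipeline* is correct and calibrated under the assumed data model, not
that the assumed model captures all features of real recordings. In
particular, published SDNN values near 170 ms are far above what a plain
2-minute RR series yields; no preprocessing reproducing them is documented,
so the generator targets physiologically conventional values instead and no
test asserts against those published magnitudes.

## Problem sizes used in the checks

The test and acceptance suites use: 10⁵ replicates for the uniform-angle
null mean (±0.01 band) and the Monte-Carlo power cross-check (±0.005 band);
100 cohorts of n = 266 for mixture recovery (median component-mean error
< 0.02); a 300-participant cohort with elevated fault rates (5%/5%/3%/3%)
for exclusion bookkeeping; 1000 null cohorts for type-I calibration of the
consistency t-test (5% ± 1.5%) and 200 effect cohorts for direction
detection (> 90%). These sizes make the stochastic bands comfortably wider
than Monte-Carlo noise while keeping a full run in minutes.

## Known limitations

* The exact angular-similarity formula of the original task software is not
  public; the resultant length is this package's definition of the score,
  and cross-study comparability of absolute score values (including the 0.42
  screener cut-off) is correspondingly uncertain.
* The age rule behind the published screened-and-matched sample is not fully
  specified; the shipped `screened_matched` spec reuses the engagement/age
  predicates (≥ 18 valid trials, no 18-year-old females) and users should
  replace it with their own predicate when matching a specific cohort.
* Belonging probabilities from the tail method are not posterior
  probabilities and do not use mixture weights; switch to
  `method = "posterior"` when a weighted interpretation is wanted.
* HRV is time-domain only, from raw RR intervals; no frequency-domain
  metrics and no beat-detection from waveforms.
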