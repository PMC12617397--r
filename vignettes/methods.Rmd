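---
title: "Methods: from heart-period logs to equivalence verdicts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from heart-period logs to equivalence verdicts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvequiv)
```

# Overview

`hrvequiv` implements an analysis chain for studies that relate resting
heart rate variability (HRV) to self-regulation and psychopathology
outcomes in clustered, multi-country adolescent samples:

1. heart-period (RR-interval) cleaning with norm-personalized artifact
   thresholds, and RMSSD / mean-HR extraction;
2. derived-item questionnaire scoring (MMAPP with embedded PHQ-A and
   GAD-7, DERS short form, DBIS) and go/no-go and delay-discounting task
   metrics;
3. multilevel multiple imputation by chained equations with passive
   derivation of BMI and totals;
4. random-intercept linear mixed models pooled by Rubin's rules;
5. TOST equivalence testing against smallest effect sizes of interest
   (SESOI) defined as 5% of each outcome's maximum score.

Because participant-level data of the motivating study design are not
distributable, the package ships a synthetic cohort generator that emulates
the data-generating structure the analysis assumes. Every stage is tested
against that generator; this vignette records the modeling choices, the
defaults, and what the synthetic results do and do not establish.

# Heart-period preprocessing

## Artifact model and detection

A recording is an ordered series of heart periods $HP_i$ (ms) with
cumulative timestamps. Two detectors are applied:

* **Absolute bounds**: beats strictly below 300 ms or strictly above
  2000 ms are physiologically implausible at rest and are flagged. Values
  exactly at a bound are kept (strict inequalities).
* **Iterative local-mean (Karlsson) detection**: beat $i$ is flagged when
  $|HP_i - L_i| / L_i > \theta$, where $L_i$ is the mean of the nearest
  non-flagged preceding and subsequent beats (endpoints use their single
  available neighbor). Passes repeat, recomputing local means over
  surviving beats, until a fixed point.

The deviation threshold $\theta$ is personalized: a preliminary RMSSD is
computed on the bounds-cleaned series and placed against adolescent resting
norms (mean 42.9 ms, SD 13.4 ms), giving categories at mean $+ k\cdot$SD
for $k \in \{-2,-1,+1,+2\}$; $\theta$ is 0.50 for very high, 0.45 for high,
and 0.40 otherwise, which avoids overcorrecting inherently variable hearts.
Three choices here were genuinely open and are fixed as follows:

* *Which RMSSD feeds categorization*: the RMSSD of the bounds-cleaned,
  pre-detection series — the only quantity available before detection runs.
* *Local mean window*: the single nearest non-flagged beat on each side,
  the smallest window consistent with "preceding and subsequent beats".
* *Cutoff ties*: a preliminary RMSSD exactly at a category cutoff takes the
  higher category (left-closed intervals), a deterministic tie rule.

Flagged beats are replaced by linear interpolation between the nearest
unflagged neighbors in beat-index coordinates (an interval series has no
natural within-gap time axis once beats are removed); flagged runs at the
ends copy the nearest clean value.

## Quality gate

Participants are excluded when more than 10 artifacts were flagged (10 is
still acceptable), when the recording spans under 240 s, or when it holds
fewer than 150 beats. The artifact cap is a study-design constant; the
duration and beat-count gates replace what was originally a visual
inspection with explicit, configurable defaults — 240 s is 80% of the
nominal 5-minute recording, and 150 beats is the count a 240-s recording
reaches at ~38 bpm, far below any plausible resting adolescent heart rate,
so the gate only removes recordings with severe beat loss.

## Features

$$\mathrm{RMSSD} = \sqrt{\tfrac{1}{N-1}\sum_{i=1}^{N-1}(HP_{i+1}-HP_i)^2},
\qquad \overline{HR} = \frac{60000}{\overline{HP}}.$$

Log-RMSSD is the natural log. Minute-wise RMSSD partitions the recording
into 60-s windows by cumulative time, assigning each beat to the window in
which it *ends* (a beat ending exactly on a boundary belongs to the earlier
window); windows with fewer than two beats are undefined. HF power
(0.15-0.40 Hz) is computed on the mean-centered tachogram resampled at 4 Hz
by cubic spline, with a Welch-type averaged periodogram (64-s Hann segments,
50% overlap). The band edges, resampling rate and estimator are package
choices — the quantity is provided for sensitivity analyses, and its
absolute scale should not be compared across estimators.

# Questionnaire and task scoring

Items are coded from 0 (MMAPP and DBIS 0-3, DERS 0-4), which makes the
instrument maxima equal the scale maxima that define the SESOI bounds
below (27, 21, 60, 24). Scores are computed on complete rows only;
pre-imputation rows with missing constituents yield `NA` rather than
prorated scores, because totals are derived passively *after* imputation.

The embedded PHQ-A collapses culturally split subquestions to their symptom
domain by taking the maximum (negative mood, sleep, motor), then adds six
single items: nine domains, range 0-27. The GAD-7 and DBIS are plain sums.
DERS reverse-codes its three positively worded awareness items
($x \mapsto 4 - x$) before summing.

**MMAPP total.** The stated rule — the maximum of the three sleep items
plus the sum of *all* items — double-counts sleep and yields a theoretical
maximum of 87 with 28 items, while the 5% SESOI of 3.75 implies a maximum
of 75. The rule is implemented verbatim with a configurable roster of
summed items; the default roster drops the three sleep items (they enter
through the max term) and the motor/anxiety duplicate item
(`restless`), giving exactly 75. The discrepancy is documented rather than
resolved; `score_mmapp_total(items, roster = mh_item_roster()$mmapp)`
recovers the fully literal arithmetic.

**Tasks.** A go/no-go false alarm is a response on a no-go trial; the
percentage divides false alarms by *total responses* (the stated
convention, kept literal), with division by no-go trial count available
behind `denominator = "nogo_trials"`. The delay-discounting percentage is
immediate choices over responded trials. Practice trials never count.

# Synthetic cohort generator

The generator is the package's stand-in for the study conditions, not a
tuning knob; its defaults are fixed once:

* three countries with a Gaussian random intercept (SD 1 outcome unit by
  default) and $n$ per country set by the caller;
* raw RMSSD lognormal with mean 43 ms and SD 13 ms, matching the norm
  reference so all threshold categories are populated;
* a continuous latent outcome
  $y = \beta_0 + u_{c} + \beta\,\log\mathrm{RMSSD} + \text{covariates} +
  \varepsilon$, $\varepsilon \sim N(0, 5)$, with $\beta = 0$ by default
  (the null structure the motivating findings describe);
* ordinal items drawn from a proportional-odds model whose trait adds the
  standardized systematic part of $y$ to unit logistic-scale noise;
  cutpoints are shared within instrument and chosen so item and total means
  sit where adolescent community samples sit (MMAPP totals in the low 20s,
  DERS mid 20s, DBIS around 5). The response-level residual correlations of
  real instruments are conventions here, not estimates;
* task metrics as binomial choice counts linked to the same trait (the
  generator does not model reaction times);
* device type per country (chest ECG everywhere in one country, mostly ear
  PPG elsewhere), demographic covariates in the ranges of a 13-15-year-old
  urban cohort;
* missingness imposed MCAR, or MAR through a logistic model on a fully
  observed auxiliary (age by default) whose intercept is calibrated to the
  target rate — a known mechanism that imputation-recovery tests can check.

Heart-period series are simulated as a mean heart period plus a sinusoidal
respiratory modulation (0.25 Hz default, the center of the HF band) and
AR(1) Gaussian noise; with no modulation and no autocorrelation the
expected RMSSD is $\sigma\sqrt{2}$, which anchors the generator's
calibration tests. Beat artifacts (spikes, merged beats, split beats) are
injected at sites at least three beats apart, with ground-truth indices
returned.

What passing tests on this generator establish: the pipeline's arithmetic,
its operating characteristics (type-I error, CI coverage, detection
sensitivity) *under the stated generating model*. What they do not
establish: robustness to non-sinusoidal respiration, ectopy clusters,
device-specific beat-detection error, or real item response structure.

# Imputation

Chained equations with type-specific conditionals: proportional-odds
regression for ordinal variables (draws from fitted category
probabilities, restricted to observed categories), logistic or multinomial
regression for nominal variables, and a Gaussian model with a country
random intercept for continuous variables, with proper parameter draws
(scaled inverse-chi-squared for the residual variance, Gaussian for the
coefficients and cluster effects) before residual noise. Defaults are
`m = 5` datasets and `maxit = 10` iterations. The cluster enters
categorical conditionals as fixed indicators and continuous conditionals
as a random intercept. Failed proportional-odds fits fall back to
predictive mean matching on a ridge-stabilized (1e-5) linear predictor
with 5 donors, logged per variable and iteration.

Open design points fixed here: the visit sequence is ascending missingness
rate; the predictor set is the covariates (age, gender, height, weight),
log-RMSSD and the cluster, plus — for instrument items — the mean of the
other items of the same instrument (a rest score). The rest score carries
the within-instrument correlation at a fraction of the cost of a
full item-by-item predictor matrix, which matters when the imputation sits
inside replicated simulations; with the weak inter-item dependence of the
generator the information loss is negligible. Log-RMSSD is treated as fully
observed: participants without valid HRV are excluded upstream, mirroring
the analysis-set construction. Chain traces (mean and SD of imputed values
per variable and iteration) are returned for convergence checks; the test
suite verifies absence of monotone drift under MCAR.

# Mixed models, pooling, and country models

Each outcome is regressed on log-RMSSD with age, gender, BMI and device
type as fixed effects and a random intercept for country, by REML (the
conventional default for this model class). Random slopes are deliberately
omitted. Gender is an unordered factor with all observed levels, including
a small nonbinary category. Per-coefficient degrees of freedom use the
Satterthwaite approximation; with three clusters and ~1100 observations
these land near the residual df.

Estimates are pooled over imputations by Rubin's rules
($\bar Q$, $W$, $B$, $T = W + (1 + 1/m)B$) with Barnard-Rubin
small-sample df. ICC is
$\sigma^2_{c} / (\sigma^2_{c} + \sigma^2_{e})$ and conditional $R^2$
uses the Gaussian variance decomposition
$(\mathrm{var}(X\hat\beta) + \sigma^2_c) / (\mathrm{var}(X\hat\beta) +
\sigma^2_c + \sigma^2_e)$. Family-wise error uses Bonferroni over the
seven outcomes (or a country's available outcome count). Country-specific
checks refit each outcome by OLS within country, dropping predictors that
are constant there (device type where a single device was used).

# Equivalence testing

Participants are dichotomized at the sample median of log-RMSSD — computed
once on the analysis sample, not per imputation (log-RMSSD is complete);
values exactly at the median go to the Low group. The group model replaces
continuous log-RMSSD with the factor (reference Low, so $B > 0$ means
higher scores under high HRV), is refitted per imputation and pooled as
above. SESOI bounds are $\pm 5\%$ of each outcome's maximum score: 3.0
(DERS), 1.35 (PHQ-A), 1.05 (GAD-7), 3.75 (MMAPP total), 1.20 (DBIS), 5.0
(percentages). TOST computes $t_L = (B - \Delta_L)/SE$ against
$P(T_{df} \ge t_L)$ and $t_U = (B - \Delta_U)/SE$ against
$P(T_{df} \le t_U)$; equivalence requires both $p < 0.05$, which is
algebraically the same as the 90% CI lying inside the bounds — the test
suite verifies the identity on randomized inputs, and one-sided p-values
reuse the pooled df of the coefficient.

# Numerical choices and degenerate inputs

* The random-intercept REML fit profiles the variance ratio on a log grid
  ($e^{-14}$ to $e^{10}$) with a boundary check at zero cluster variance;
  designs are guarded with a $10^{-10}$ relative ridge.
* RMSSD of a constant series is exactly 0; log-RMSSD is then undefined and
  reported as `NA`.
* A series shorter than 3 beats cannot be screened and is excluded as an
  implausible beat count; interpolation requires at least 2 clean beats.
* Rubin pooling with zero between-variance returns the complete-data df.
* `simulate_hp_series` clamps beats at a 1 ms floor; with the documented
  parameter ranges the clamp is never active.

# Problem sizes used in the shipped checks

The replicated operating-characteristic checks run at $n = 300$ (3 x 100,
1000 replicates) for type-I error and $n = 900$ (3 x 300, 300 replicates)
for coverage of a true effect $\beta = 2$, each with MAR missingness on
weight at 5% and the full `m = 5`, `maxit = 10` imputation; the
null-equivalence reproduction uses $n = 1110$ (3 x 370), comparable to the
motivating analysis set. These sizes give Monte-Carlo error small enough to
resolve the tested bands (e.g. binomial SE ~0.7 percentage points for a 5%
rejection rate at 1000 replicates) while keeping the default test run at
desk scale. Acceptance-band endpoints and generator defaults were fixed
before the checks were run and are not adjusted to outcomes.

# Known limitations

* The generator's respiratory modulation is a single sinusoid; real RSA is
  broadband and amplitude-modulated.
* Ordinal conditionals assume proportional odds both in generation and
  imputation — congenial by construction, which flatters imputation
  performance relative to real data.
* The country random intercept is estimated from three clusters; variance
  components at three clusters are noisy, and singular fits are expected
  and flagged rather than suppressed.
* HF power depends on estimator settings; only within-package comparisons
  are meaningful.
* The pipeline does not model reaction times, respiration, posture, or
  circadian effects.
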