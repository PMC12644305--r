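---
title: "High-dimensional propensity scores: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-dimensional propensity scores: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Active-comparator cohort studies in electronic health records (EHRs)
compare outcomes between two clinically interchangeable treatments, here
an ICS/LABA-type combination against a LABA/LAMA-type combination in a
COPD population followed over a short, fixed window.  The central threat
is confounding by indication: disease severity and frailty influence both
which treatment a patient receives and their outcome risk, and neither is
recorded directly.  Investigator-specified ("prespecified") covariates
capture part of this; the high-dimensional propensity score (HDPS)
approach additionally mines the coded record itself — diagnoses,
prescriptions, hospitalisations — for proxy variables that track the
unmeasured constructs.

`hdps` implements that pipeline end to end:

1. **Code harmonization** (`map_and_truncate_observations()`,
   `map_prescriptions()`): raw clinical codes are mapped to 3-character
   ICD-like classes, drug codes to 6-character formulary paragraphs (with
   a chapter-prefix fallback), unmapped codes are dropped and reported,
   and codes that define the exposure or the outcome are excluded.
   Codes defining prespecified covariates are *not* excluded.
2. **Recurrence covariates** (`build_recurrence_covariates()`): for each
   (dimension, code), binary indicators of occurrence at least once, at
   least the median number of times, and at least the 75th-percentile
   number of times within a 12-month assessment window, thresholds
   computed among patients with at least one occurrence.  For the
   primary-care observation dimension, "once" is redefined as *ever
   recorded before index*, because chronic conditions are not re-recorded
   at every consultation.  No marginal-prevalence filter is applied, so
   rare but strong confounder proxies stay in the pool.
3. **Prioritisation** (`score_covariates()`, `rank_covariates()`): each
   candidate is scored with the Bross bias multiplier
   $\mathrm{bias} = \frac{P_{C1}(RR_{CD}-1)+1}{P_{C0}(RR_{CD}-1)+1}$,
   where $P_{C1}, P_{C0}$ are the covariate's prevalences in the exposed
   and unexposed arms and $RR_{CD}$ its relative risk with the outcome,
   estimated in the unexposed stratum.  Ranking is by
   $|\log(\mathrm{bias})|$.  Covariates behaving like instruments
   ($|\log RR_{CE}| > 1.1$ and $|\log RR_{CD}| < 0.5$) are flagged and
   removed, since adjusting for instruments amplifies bias.
4. **Weighting** (`fit_propensity_model()`, `stabilized_weights()`,
   `trim_common_support()`): logistic propensity model on prespecified
   plus top-$k$ covariates; stabilized ATE weights $p_E/PS$ and
   $(1-p_E)/(1-PS)$; trimming to the propensity range where both arms are
   represented.
5. **Outcome models** (`weighted_cox_hr()`, `weighted_logistic_or()`,
   `weighted_risk_difference()`, `weighted_survival_curves()`,
   `schoenfeld_ph_check()`): IPT-weighted Cox (Efron ties, robust
   sandwich variance), weighted logistic and risk-difference estimators,
   weighted Kaplan–Meier curves, and a Schoenfeld-residual diagnostic
   that never alters the estimate — under non-proportionality the hazard
   ratio is read as a period average.
6. **Sensitivity machinery** (`hdps_k_sweep()`,
   `one_by_one_trajectory()`): the covariate count $k$ is varied over a
   grid (100, 250, 500, 750, 1000 in the motivating application), and
   ranked covariates are added one at a time with the maximum weight and
   per-arm effective sample size $(\sum w)^2/\sum w^2$ recorded at every
   step, which localises the instability caused by rare covariate
   combinations receiving extreme weights.

`hdps_fit()` composes stages 1–5 and returns a classed object with
`print`, `summary`, `coef`, `predict` and `plot` methods; `k = 0`
reproduces the conventional (prespecified-only) analysis exactly.

## What the synthetic generator emulates

Real source data of this kind (linked primary-care, hospital and death
records) cannot be redistributed, so the package ships a generator
(`sim_config()`, `simulate_hdps_data()`) that reproduces the *statistical
structure* the method assumes, with every parameter inspectable:

- **Two latent variables**, severity and frailty, standard normal,
  entering the exposure log-odds (defaults 0.5 and 0.25) and the outcome
  log-hazard (0.8 and 0.6).  They are deliberately withheld from the
  analysis surface: the pipeline only ever sees their proxy codes.
- **Prespecified covariates** (age group, sex, BMI, smoking, ethnicity,
  deprivation quintile, comorbidities, vaccinations, exacerbation
  history) drawn with prevalences loosely matching the motivating
  cohort's baseline table, some with exposure and/or outcome effects of
  their own — past asthma is the strongest treatment-channeling
  covariate, which reproduces the familiar large unweighted imbalance.
- **Proxy codes**: 20 confounder-proxy codes per care dimension, each
  firing through a steep threshold logistic (slope 4) in one latent, with
  cut points spread over the latent's 0.20–0.95 quantiles.  A battery of
  threshold indicators at spread cut points forms a step-function basis
  for the latent, which is what makes a top-100 HDPS able to reconstruct
  and remove latent confounding.  Occurrence counts on `{1..10}` also
  shift with the latent, so the sporadic/frequent levels carry signal.
- **Instrument codes** (one per dimension) firing on arm membership only
  (prevalence 0.30 unexposed vs 0.96 exposed, exposure RR ≈ 3.2, above
  the $e^{1.1}$ cutoff), with no outcome association by construction.
  They exist to exercise the instrument-exclusion rule; making them
  common keeps their null outcome-RR precisely estimable at ~200 events,
  so flagging is reliable rather than borderline.
- **Noise codes** (20 per dimension) independent of everything.
- **Exposure- and outcome-defining codes** (drug-class paragraphs;
  a "U07"-style outcome chapter that leaks outcome status) so the
  exclusion stage removes something real.
- **Outcome**: exponential survival with log-linear hazard, administrative
  censoring at 184 days, 5% independent random censoring, and a baseline
  hazard auto-calibrated to a ~1% cumulative event risk — the
  rare-outcome regime in which one-by-one covariate sensitivity is known
  to be volatile.  Event times are rounded up to whole days, producing
  ties (hence Efron's approximation in the Cox fit).
- **Plumbing stressors**: two raw aliases per harmonized code
  (many-to-one mapping), ~5% of raw codes deliberately unmapped, every
  fifth prescription code reachable only through the fallback table,
  event dates uniform on 1–400 days before index (so some fall outside
  the 365-day window), missing BMI/ethnicity/IMD at realistic rates, and
  a triple-therapy flag among the exposed (probability increasing with
  severity) to support both cohort definitions.

What the generator does **not** emulate: real vocabulary structure,
calendar time, treatment-episode dynamics, time-varying confounding,
competing risks, regional clustering, or outcome misclassification.
Passing tests therefore demonstrate that the machinery is correct and
that the method removes *this* kind of proxy-expressed confounding; they
say nothing about vocabulary-mapping quality or design pitfalls in real
data.

## Numerical and design choices

- **Recurrence thresholds.**  The median/75th-percentile thresholds are
  computed with a nearest-rank ceiling rule ($k$-th smallest positive
  count, $k = \lceil q\,m \rceil$) by default — integer thresholds on
  integer counts, no interpolation ambiguity — with R's interpolating
  type-7 quantile available via `quantile_rule = "type7"`.  Ties at the
  threshold qualify (`>=`).
- **Degenerate levels.**  When all positive counts equal the threshold,
  once/sporadic/frequent collapse to identical columns; within-code
  deduplication keeps the lowest level so the propensity design never
  contains exact duplicates.  Deduplication is within-code only.
- **Bross conventions.**  $RR_{CD}$ is estimated in the unexposed stratum
  (configurable to the full cohort); any 2×2 with a zero cell gets 0.1
  added to every cell of that table, keeping rare-outcome covariates
  scoreable; $RR_{CD} < 1$ is inverted inside the formula so protective
  and harmful associations rank symmetrically; exact ties in
  $|\log \mathrm{bias}|$ break lexicographically on the covariate id for
  cross-platform reproducibility.  Prioritisation is outcome-specific and
  recomputed per outcome and cohort definition.
- **Separation and collinearity.**  The propensity fit drops aliased
  columns with a warning (rank deficiency is expected when nested
  recurrence levels coincide in a trimmed subsample) and errors on
  (quasi-)separation, naming the offending columns, because a separated
  model cannot yield usable weights.
- **Weights.**  Stabilization uses the marginal exposure prevalence of
  the trimmed analysis set; no truncation or capping is applied —
  extreme weights are *reported* (max weight, effective sample size)
  rather than hidden, because weight pathology is itself a finding of the
  one-by-one sensitivity analysis.
- **Trimming.**  Bounds are inclusive; the conventional and HDPS
  analyses each trim on their own propensity score.  Re-trimming the
  retained set leaves the bounds nested and can shave a handful of new
  boundary patients (with continuous scores the bound-attaining patient
  of one group is removed from the other); the pipeline applies the trim
  exactly once per analysis and reports exclusion counts.
- **SMDs.**  Binary/continuous columns use
  $|m_1-m_0|/\sqrt{(v_1+v_0)/2}$ with frequency-weight variances about
  the weighted mean (denominator $\sum w - 1$); categorical covariates
  use the Mahalanobis-type multi-category statistic over the $K-1$
  level-proportion vectors, so a baseline table prints one SMD per
  categorical covariate.  Zero pooled variance with unequal means is
  reported as `Inf`, a flagged value.  0.1 is used throughout as the
  adequacy threshold.
- **Variances.**  All weighted outcome models report robust sandwich
  standard errors; the risk difference uses a ratio-linearisation
  influence function (stratified bootstrap available), and 95% intervals
  are Wald-type on the log scale for ratio estimands.
- **Missing data.**  Missing BMI is set to the "normal" category
  (extreme values are more likely to be recorded), missing ethnicity
  becomes an "Unknown" level, missing deprivation quintile drops the row
  (logged); missingness anywhere else is an error because no rule covers
  it.  Multiple imputation is out of scope.
- **One-by-one trajectories** refit the propensity model from scratch at
  each step, with the ranking computed once and frozen before the loop;
  a shortcut that reuses coefficients would confound the trajectory with
  optimizer warm starts.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route:
contingency statistics and the bias multiplier against brute-force
arithmetic on random 2×2×2 tables; the weighted Cox estimate against
direct maximization of the weighted partial likelihood on ≤20-patient
fixtures; the propensity fit against `glm`; the weighted Kaplan–Meier
drop against its hand formula; the published past-asthma imbalance
(prevalences 27.7% vs 11.9%) against its printed SMD of 0.404.

The headline scientific check is a replicated null-recovery study under
the generator defaults: 50 cohorts of 20 000 patients, true conditional
hazard ratio 1, confounding expressed only through proxy codes.  The
conventional analysis is biased away from the null (mean log HR ≈ 0.4)
while the top-100 HDPS mean lies within two Monte-Carlo standard errors
of zero; in the same replicates, true-confounder codes out-rank noise
codes and instrument codes are flagged essentially always, weighting
brings every propensity-model covariate below SMD 0.1, the mean
stabilized weight is within 0.02 of 1, and trimming removes well under
1% of patients.  These sizes (50 × 20 000 in the test suite; 30
replicates in the acceptance script) keep the full validation run in the
minutes range on one core while leaving Monte-Carlo error well below the
conventional-analysis bias being demonstrated.  The removal is not
mathematically complete: binary recurrence indicators cannot perfectly
reconstruct a continuous latent, and a top-100 selection cannot hold
every informative column, so a small residual bias (of order a few
hundredths on the log scale, against ~0.5 before adjustment) persists
and is visible in large replication batches.

## Known limitations

- The Bross statistic handles binary covariates, exposures and outcomes
  only; continuous confounders enter solely through their coded proxies,
  and follow-up time is ignored during prioritisation (acceptable here
  because censoring is low and Cox and logistic estimates nearly
  coincide).
- The generator's latents are one-dimensional and time-fixed; real
  severity is neither.
- With rare outcomes, covariates far down the ranking can still move the
  estimate when a rare covariate combination meets an outcome event —
  the one-by-one trajectory makes this visible but cannot prevent it.
- Instrument flagging depends on an estimable covariate–outcome RR; very
  rare instrument-like codes can escape the cutoffs, enter the model,
  and widen weights.  The diagnostics (max weight, effective sample
  size) are the guard rail.
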