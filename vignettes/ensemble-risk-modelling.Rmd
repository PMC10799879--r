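---
title: "Ensemble transfer learning for suicide-risk prediction: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble transfer learning for suicide-risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

riskpipe implements, end to end, an ensemble transfer-learning workflow for
predicting death by suicide — and a combined outcome of suicide, suicide
attempt and drug overdose — from longitudinal electronic-medical-record (EMR)
features. Because real EMR data of this kind are access-restricted, the
package ships a seeded synthetic-EMR generator with a *known* ground-truth
risk model, so every downstream stage (outcome classification, cohort
construction, encoding, model fitting, stacking, evaluation) is testable
against the truth that generated the data.

## The modelling problem

Suicide is rare, its recording is ambiguous, and the clinically richer
surrogate outcomes (attempts, overdoses) are strongly confounded by how often
a patient is seen. The workflow addresses this with three coupled ideas:

1. **A combined outcome built by priority.** Coded events are classified by
   anchored, case-insensitive regular expressions over ICD-9/ICD-10 codes
   (`code_patterns()`); suicide-related matches on death-cause records mean
   death by suicide, on clinical records a suicide attempt. Within a study
   window each patient contributes at most one label: suicide if present,
   else the first attempt, else the first overdose (`build_combined_outcome()`).

2. **Multiple study designs over one shared feature clock.** All designs
   observe the 7.5 years before a *time of prediction*, split into eight
   half-open calendar-month bins of widths 3, 3, 6, 6, 12, 12, 24, 24 months
   (most recent first; `make_time_bins()`). Because the clock is identical
   everywhere, a model trained on one design can score any other.
   - *Rcc*: a matched retrospective nested case-control design. The time of
     prediction sits exactly 45 days before the (pseudo-)outcome. Controls
     are drawn from the case's date-of-birth partition by sampling patients
     with probability proportional to their visit count within the span of
     case outcome dates, and a random such visit becomes the pseudo-outcome.
     This matches on age and on healthcare utilization by construction.
   - *Calendar cohorts* (C15/C17-style): everyone with a visit in the 3
     months before a fixed date; outcomes counted from 7 days to 2 years
     after it.
   - *Event-triggered time-to-event cohorts* (CoxMH/CoxVisit-style): the
     clock starts at the first psychiatric evaluation or office visit in a
     3-year initiation window; follow-up is right-censored on death only,
     never on loss to contact.

3. **Ensemble transfer learning.** Base learners trained on the designs
   above score the fine-tuning cohort; an unpenalized logistic regression
   stacks seven base scores with ten design-sensitive covariates (sex, race,
   ethnicity, young/old age flags, any-bin chronic pain, suicide ideation,
   prior attempt, prior overdose, and the utilization index). Two ensembles
   are kept: a combined-outcome ensemble excluding the suicide-trained
   calendar base, and a suicide ensemble excluding the combined-trained one
   (seven bases each). All linear fits report even/odd-averaged coefficients;
   every evaluation score comes from the half the row was not trained on.

## The synthetic generator and what it does (and does not) emulate

`simulate_population()` draws patients (DOB uniform 1930–1995, 90% male),
gives each a yearly visit intensity from a log-normal (meanlog `log(3)`,
sdlog 0.8) driving a homogeneous Poisson visit process over 2000–2021, emits
75 diagnosis variables plus 10 medication/procedure variables per visit with
fixed probabilities, and measures blood pressure, hemoglobin and PHQ surveys
at a subset of visits. Outcomes come from a discrete-time yearly Bernoulli
hazard whose logit is linear in the trailing eight-bin feature state, age
(per decade, centred at 65) and the count of active diagnosis-variable×bin
cells. Because the utilization effect is positive, confounding by healthcare
contact exists *by construction*, which is exactly what the Rcc matching must
absorb. Suicide is terminal and unique; attempts and overdoses recur and feed
back into later feature states. No event postdates death.

Deliberate departures from clinical reality, chosen once for desk scale:

- Outcome rates are elevated (defaults give roughly 0.25% two-year suicide
  fractions in calendar cohorts and ~15% cumulative attempts over 22 years)
  so cohorts of 2,000–20,000 patients retain enough cases to train all five
  learners. `calibrate_intercepts()` retunes intercepts to any target
  cumulative prevalence when a scenario requires an exact rate.
- The generator's truth uses day-width bins (91/183/365/730 days); the
  encoder uses calendar months. The mismatch is intentional: truth is
  self-consistent, and estimators are only ever compared to it statistically.
- Visit-type tags, representative ICD strings (so the regex layer is really
  exercised), one synthetic area-level covariate in place of census matching,
  and an optional recording changepoint (attempt/overdose events after a
  fixed date kept with probability 0.5) emulating the ICD-9→ICD-10
  discontinuity; off by default.

Passing tests on these data show the *machinery* is correct — sampling
designs, leakage discipline, recovery of known parameters — not that the
fitted coefficients transfer to any real population.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| Rcc gap | 45 days | leakage guard between prediction and outcome |
| prospective exclusion | 7 days | keeps near-term events while blocking leakage |
| controls per case | 4 | matched design's power/cost balance |
| DOB partitions | 100 | even/odd train/test separation |
| bins | 3,3,6,6,12,12,24,24 months | acute-to-distal resolution over 7.5 y |
| RF | 500 trees, √p, min leaf 100 | reference forest settings |
| network | 1024/512/256 ReLU | reference architecture (`learner_config()`); the pipeline profile uses 128/64/32, sized to desk-scale cohorts |
| lasso selection | 1-SE rule | see below |
| calibration bin width | 0.5 log-odds | readable curves; configurable |
| top strata | 1%, 0.1% | screening-relevant tail fractions |

**Lasso selection rule.** The penalty is chosen by cross-validated deviance
under the one-standard-error rule rather than at the deviance minimum.
Measured on a sparse generator (10 true coefficients, n = 20,000), the
minimum-deviance rule admits 16–27 spurious variables while the 1-SE rule
recovers exactly the true support; since the package leans on the selected
support as a scientific readout, parsimony wins. `select = "lambda.min"`
remains available.

**"Young or old" fine-tuning flags.** Implemented as two indicators, age < 55
and age > 65 — the thresholds used in the subgroup analyses; the stacking fit
weighs them independently.

**Demographics across bins.** Cross-sectional variables enter the design once
by default; `replicate_demographics = TRUE` reproduces the display convention
of splitting them evenly across the eight bins. Both readings are supported
because the underlying fitted models are equivalent up to coefficient
scaling.

**Two utilization statistics.** The fine-tuning `usage` index counts active
(diagnosis variable × bin) cells (0–600); `utilization_bins()` counts bins
with any diagnosis present (0–8) and is used for calibration subgrouping,
with tertile cutpoints among patients above one active bin. They are related
but not interchangeable, and both are exported.

## Numerical and degenerate-input choices

- Intervals are half-open `[start, end)` everywhere; an event on a bin
  boundary belongs to the more recent bin, and an event dated at the time of
  prediction is outside the window. Events dated *after* a row's prediction
  time are a hard leakage error in the strict encoder; `audit_leakage()`
  re-derives the binary block by brute force to verify the full pipeline.
- Combined-outcome ties on one date resolve by component priority then by
  within-patient event id — labels are independent of row order.
- Unpenalized stacking falls back to a tiny ridge (1e-6) under separation,
  with a warning; rank-deficient columns are dropped with a message and
  recorded as zero coefficients.
- Naive Bayes uses Bernoulli likelihoods with additive smoothing 1 over the
  binary columns only; it is linear in log-odds, so it averages and scores
  through the same path as the other linear kinds.
- The feed-forward network is implemented in-package (matrix arithmetic,
  minibatch Adam, early stopping on a validation slice of the training
  half); Cox models with zero events, single-class targets, and all-constant
  designs fail loudly rather than silently.
- Calibration tables report both `expected` (logistic value at the bin
  centre, the plotted reference) and `expected_mean` (mean predicted
  probability of the rows in the bin). Interval-coverage checks use
  `expected_mean`: with wide, well-filled bins the centre value carries a
  within-bin discretization bias larger than an exact binomial interval.

## Problem sizes used by the shipped checks

The test suite exercises populations of 200–20,000 patients; the end-to-end
pipeline fixture uses 3,000 patients with a compact learner profile, and the
acceptance script runs the full pipeline at 12,000 patients plus dedicated
scenarios at n = 50,000 (stacking recovery, ensemble dominance) and
n = 100,000 (calibration, risk concentration). These sizes were chosen as the
smallest at which the statistical claims under test are stable.

## Known limitations

- The generator's visit process is homogeneous within patient; real
  utilization is bursty around illness episodes.
- Diagnosis emissions are independent across variables given the visit, so
  comorbidity correlation structure is absent.
- The drift scenario induces recording drift (thinned attempt/overdose
  recording), not covariate drift.
- TabNet-style attention models are out of scope; the base-model registry is
  a named list, so an eighth model can be registered without code changes.
- Real-data coefficient values and headline c-statistics from operational
  EMR cohorts are not reproducible from synthetic data and are not targets
  of any shipped check.
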