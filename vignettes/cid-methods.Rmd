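---
title: "Deriving and analyzing clinically important deterioration endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and analyzing clinically important deterioration endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdcid)
```

## The endpoint

COPD is heterogeneous: spirometry, health status and exacerbations each
capture a different facet of worsening, and single-outcome analyses miss
patients who deteriorate on another axis. The *clinically important
deterioration* (CID) composite classifies a patient as deteriorated at the
first occurrence of any of three components, each anchored at an accepted
minimal clinically important difference:

* **FEV1**: a decrease from baseline of >= 100 mL in pre-dose (trough)
  forced expiratory volume in 1 s at a scheduled visit;
* **SGRQ**: an increase from baseline of >= 4 points in St George's
  Respiratory Questionnaire total score (0--100, higher = worse);
* **Exacerbation**: a moderate-to-severe COPD exacerbation with onset after
  the first dose of study medication.

Time to first CID is the minimum of the component event times; components
tied at the minimum are all recorded. Both measurement boundaries are
inclusive (`cid_thresholds()` holds the defaults; a drop of exactly 100 mL
flags). Comparisons of measurements against thresholds use an absolute
tolerance of 1e-9 so that double-precision subtraction cannot unflag an
exact boundary, while a value 1 mL (or 0.01 SGRQ unit) short of the
boundary never flags.

A *sustained* CID separates transient fluctuation from persistent
worsening. A measurement component is sustained at the earliest visit *v*
where it is flagged and either

a. it is also flagged at the next scheduled visit exactly one visit
   interval (4 weeks) later, or
b. it is flagged at >= 50% of all *available* subsequent visits.

A qualifying exacerbation is sustained by definition, at its onset day, so
per-component first and sustained exacerbation counts coincide — this
identity is asserted on every input in the test suite.

### Interpretations the written rule leaves open

The sustained definition required four decisions, which we fixed as
follows and exercise explicitly in tests:

* *"Consecutive visits 4 weeks apart"* means adjacent on the nominal
  schedule. If the intervening measurement is missing, visits 8 weeks
  apart do **not** satisfy branch (a); branch (b) still offers a path.
* The *available subsequent visits* of branch (b) include the triggering
  visit itself, and count only visits (at or after *v*, through last
  contact) with a non-missing measurement for that component: "available"
  must be observable to form a denominator. A corollary worth knowing: a
  flag at a patient's final available visit is trivially sustained
  (1/1 = 100%).
* Branch (b) is evaluated retrospectively with the full follow-up known,
  as befits a post-hoc analysis, not adaptively at each visit.
* SGRQ uses the same two-branch rule as FEV1; nothing in the definition
  differentiates them, and the sharp drop of SGRQ events from first to
  sustained that this produces is consistent with reported behaviour of
  the endpoint.

The rule engine is verified against an exhaustive brute-force evaluation
of the written rule over all 2^6 flag patterns on a 6-visit grid, with and
without a missing visit at each position, through both measurement
components.

## Censoring

Day 1 is the day of first dose; all event and censoring times are integer
days from first dose, with visit day = 7 x visit week (days give the
exacerbation component its natural resolution). A patient with no event is
censored at the end-of-study day if they completed, or at the last contact
day if they discontinued early. An event on the discontinuation day counts
as an event (event precedence over censoring). Baseline is the pre-dose
measurement at randomization and is never reset.

## Survival methods

`km_estimate()` computes the product-limit estimator with the median time
to event, 25%/75% quartiles, and a 95% CI for the median from the log-log
transformed Greenwood variance (the common default; no method is mandated
by the endpoint definition). `logrank_test()` is the unweighted two-group
log-rank chi-square on 1 df. `cox_fit()` maximizes the partial likelihood
with the **Efron** approximation for ties: FEV1 and SGRQ events land on a
28-day visit grid, so ties are heavy and Efron is markedly more accurate
than Breslow there. Pooled analyses stratify the baseline hazard by study
(`strata_by_study = TRUE`), because 12-, 26- and 52-week studies cannot
plausibly share one baseline hazard; a single-stratum fit equals the
unstratified fit (tested). The headline contrast model adjusts for sex,
age group (<65 / >=65), GOLD severity, current smoking and eosinophil
group (<300 / >=300 cells/uL, boundary to the high group), mirroring
standard covariate sets for this endpoint; `adjust = FALSE` gives the
treatment-only model. All p-values are two-sided at 0.05: Wald for Cox
terms, chi-square for the log-rank. Because published tables of this
endpoint do not identify which of the two tests produced each printed
p-value, `summarize_events()` emits both per row.

Estimation is delegated to the `survival` package; the test suite checks
it against independent oracles — hand product-limit arithmetic, explicit
risk-set O-E/V computation, and direct numerical maximization of the
written partial likelihood — plus a 5,000-replicate type-I-error
simulation for the log-rank test and a 200-replicate CI-coverage
simulation for a planted hazard ratio of 0.5 at n = 2,000.

## Subgroups and reporting

`subgroup_specs()` ships the nine standard splits (sex, age, smoking,
prior-year exacerbation, ICS use, SGRQ <=25/>25, BDI <=7/>7, severity,
eosinophils <300/>=300). Subgroup hazard ratios come from a
treatment-only, study-stratified Cox fit within the level: whether
published subgroup models adjust for the other covariates is unstated, so
the unadjusted-within-level variant is the default and the adjusted one is
a flag. A GOLD A+B vs C+D split built from the programme's surrogates
(severity or prior exacerbation as the risk axis) is implemented but
disabled by default, mirroring the judgement that a low exacerbation
burden makes that classification unrepresentative. Event-summary
percentages are count/arm-N rounded half-away-from-zero to one decimal —
the convention that reproduces printed trial tables exactly — and the
summary's percentages always recompute from its own counts (tested
property). `values_at_event()` reports mean +/- SD of the triggering
measure at baseline and at the triggering visit among component-event
patients, with Welch t-tests between arms; single-patient cells report
SD 0 at n = 1 rather than NA so downstream layout code need not
special-case them.

## The synthetic cohort generator

No patient-level data from the pooled programme are deposited, so the
package carries a generator that emulates the *structure* the analysis
assumes — it is first-class, tested code, not a fixture.

* **Designs**: four studies (12, 26, 26, 52 weeks) on a 4-weekly visit
  grid, pooled; arm allocation ~63:37 active vs active-comparator, with an
  optional placebo arm at the pooled proportions. A 26-week study's end
  (day 182) falls after its last scheduled visit (week 24); completers are
  censored at the end-of-study day.
* **Baselines** target the pooled population moments: pre-dose FEV1 mean
  1.3 L (SD 0.47), SGRQ 48.0 (17.66), 74% male, 41% current smokers, 25%
  with a prior-year exacerbation, 38% GOLD-severe, 55% ICS use, BDI 6.2
  (2.17), age 63.9 (8.9), eosinophils gamma with mean 270 / SD 184
  cells/uL (the published table's "2.7 (1.84)" read as 10^2 cells/uL — the
  raw scale is biologically impossible and the >=300 cells/uL subgroup
  boundary requires it). FEV1 is drawn lognormal with moments matched
  exactly to the targets: FEV1 is positive and right-skewed, and a
  truncated normal would bias the mean by ~4 mL against a 3-SE acceptance
  band of ~14 mL at n = 10,000. SGRQ is normal clipped to [0, 100]
  (clipping shifts the mean by ~+0.02 units and the SD by ~-0.07 — both
  negligible at the tested scale).
* **Trajectories**: visit value = baseline + arm effect + slope x t +
  AR(1) noise (lag-1 correlation 0.4), SGRQ clipped to [0, 100].
  Within-patient noise SDs default to clinically realistic test-retest
  variability — 0.11 L for trough FEV1 and 4.5 SGRQ units — chosen so the
  implied component CID frequencies land in the plausible range for this
  population (roughly 35--45% FEV1, ~25% SGRQ, ~60% any-component first
  CID over pooled follow-up) rather than the implausible rates a larger
  measurement SD produces. Arm effects default to +0.06 L FEV1 / -3 SGRQ
  for both active arms (equal by design, emulating an
  equivalence setting) and 0 for placebo.
* **Exacerbations**: a gamma-frailty-mixed Poisson process (dispersion 0.5
  gives the over-dispersion real exacerbation counts show; tested),
  annual rates 0.45/patient-year on active arms and 0.75 on placebo,
  onset days uniform over follow-up, severity moderate/severe 80/20 —
  the CID rule treats them identically. Exposure converts days at 365.25
  days/year.
* **Dropout**: non-informative exponential hazard (0.25/year, giving the
  ~6--22% discontinuation a 12-to-52-week study typically sees), rounded
  up to the next scheduled visit; a per-visit missingness probability
  (default 0) exists to exercise the sustained-rule edge cases. An
  informative-dropout coupling is deliberately *not* simulated by
  default, since the survival methods assume independent censoring.
* **Determinism**: one global seed; each patient's draws come from a
  substream derived from (seed, patient index), so cohorts are
  byte-identical across reruns and do not depend on loop order.

Measurements are rounded at generation to clinical resolution (FEV1 to
the mL, SGRQ to 0.01), which also makes CSV round-trips exact.

### What the generator does not emulate

Baseline covariates are drawn independently: the real correlations between
FEV1 % predicted, GOLD grade, symptoms and exacerbation history are not
modelled, so subgroup analyses on synthetic data test machinery, not
epidemiology. Trajectories are stationary around a linear trend — no
post-exacerbation rebound, no seasonal structure, no learning effects on
SGRQ. Passing tests therefore demonstrate that the pipeline computes the
endpoint and its analyses correctly under the stated stochastic model, not
that any clinical conclusion transfers to real cohorts; published hazard
ratios from the real patient-level data are qualitative context only, not
numeric targets.

## Problem sizes and numerical choices

The test suite checks simulator calibration on a 10,000-patient cohort
(3-SE bands), log-rank size on 5,000 null replicates of 50+50, Cox
coverage on 200 replicates of n = 2,000, and end-to-end properties on
cohorts of 400--3,400 patients — sizes at which every moment band and
rejection-rate band quoted above has meaningful power while the whole
suite stays fast. Percent rounding is half-away-from-zero (base R rounds
half-to-even and cannot reproduce printed trial percentages such as
57.75 -> 57.8). Ties at the first-CID minimum are kept, never broken, so
per-component counts may sum to more than the overall count but never
less (tested invariant).

## Limitations

Events detected on a 4-week grid are interval-censored; like the analyses
this package emulates, we treat the visit day as the event day and fit
right-censored models, which biases absolute event times slightly late
but affects both arms alike. Competing risks (death, discontinuation
causes) and recurrent events are out of scope. The sustained-rule
interpretations listed above are choices; alternative readings change the
sustained counts and are easy to probe through `cid_thresholds()` and the
missingness machinery.
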