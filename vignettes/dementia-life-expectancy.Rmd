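---
title: "Average life expectancy with dementia: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average life expectancy with dementia: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

demlife estimates the individual-level burden of dementia from quarterly
health-insurance claims panels: how many years people live after a dementia
diagnosis, how many years a same-aged person without dementia would live,
and how both quantities move when incidence and mortality change between two
calendar periods.  This vignette documents the model, the conventions and
the numerical choices, and states what the package's validation studies do
and do not demonstrate.

## The illness-death model

The core is a three-state Markov (illness-death) model on single-year ages
65 to 100 with states *non-dementia*, *dementia* and *dead*, and three
age-specific transition hazards per sex and period:

* `DI(x)` — dementia incidence (non-dementia to dementia),
* `DM(x)` — mortality with dementia,
* `non-DM(x)` — mortality without dementia.

Hazards are constant within each single-year age interval, so all survival
and sojourn quantities have exponential closed forms; this convention gives
exactly testable special cases and is the standard rates-to-probabilities
conversion.  With radix `l_nd(65) = 1`, the non-dementia survivors update
as `l_nd(x+1) = l_nd(x) exp(-h(x))` with total exit hazard
`h(x) = DI(x) + non-DM(x)`, and the interval's exits are split
proportionally to the cause-specific hazards.  The decrement
`d(x) = l_nd(x)(1 - e^{-h(x)}) DI(x)/h(x)` counts new dementia cases in
`[x, x+1)`; non-dementia deaths take the remainder, so the accounting
identity `l_nd(x) = l_nd(x+1) + d(x) + deaths_nd(x)` holds to machine
precision at every age (the test suite asserts it below `1e-15`).  New
dementia cases enter the dementia state at mid-interval for occupancy and
person-years accounting; the state then evolves under `DM(x)`.  The table
is truncated at age 100: every expectancy is a *temporary* expectancy
between x and 100, with no open-ended interval.

Two remaining-life quantities are computed by backward recursion:

* `e(x)` — expected years lived between exact age x and 100 by a person in
  the dementia state at x (survival under `DM` alone);
* `e*(x)` — expected years lived between x and 100 by a person
  dementia-free at x.

For constant `DM(x) = m` the recursion reproduces
`e(x) = (1 - e^{-m(100-x)})/m` exactly, which the tests check at `1e-12`.

### What `e*(x)` counts

The dementia-free expectancy admits two readings, and the package
implements both (`nondem_mode` in `state_expectancies()`):

* `"threestate"` (default): all remaining years alive of a currently
  dementia-free person, including years lived after a *later* dementia
  onset.  This makes the excess-life-years-lost contrast a like-for-like
  comparison between two persons of the same age who differ only in
  current disease status.
* `"nondem_hazard_only"`: survival under `non-DM(x)` alone, i.e. years
  lived while dementia-free.

The default was a genuinely open design choice; the three-state reading
was adopted because the alternative conflates "not having dementia now"
with "never getting dementia", which overstates the contrast.

### Onset-age-weighted averages

Life expectancy *at 65* assumes everyone falls ill at 65.  Instead, each
age's expectancy is weighted by the model's own distribution of age at
onset: with `w(x) = d(x) / Σ d(x)`,

* ALE with dementia: `Σ e(x) w(x)`,
* ALE without dementia: `Σ e*(x) w(x)` (same weights),
* excess life years lost: `LYL = ALE_nondem − ALE_dem`,
* ratio `R = ALE_dem / (ALE_dem + ALE_nondem)` — the proportion of the
  total remaining years that are lived with dementia.

The decrements are normalised: with radix 1 the raw `d(x)` sum to the
lifetime onset risk, not to 1, and only the normalised weights keep the ALE
interpretable in years.  The age-specific expectancies entering the sum are
taken at exact integer ages with weight `d(x)`, while occupancy accounting
uses mid-interval entry; both conventions are deliberate and consistent
with the discrete printed form of the estimator.

## From claims records to rates

**Case definition.**  Dementia is identified by ICD-10 prefixes G30, F00,
F01, F02, F03 and F05.1, matched on dot-stripped codes (`F051` matches
`F05.1`; `F05.0` does not).  A record is *admissible* when it is an
outpatient diagnosis marked verified, or an inpatient discharge or
secondary diagnosis.  A person becomes a case when they accumulate two
admissible records — in the same quarter or anywhere in the observation
period — or a single admissible record in the quarter of death.  The
two-records wording in claims-validation practice is ambiguous about
whether the records must come from different occasions; occurrence
counting over the observation period is used here because occasions are
not identifiable in the data model.  The first valid diagnosis is dated to
the person's earliest admissible record.

**Calendar conventions.**  Vital events carry month precision, diagnoses
quarter precision.  A quarter-resolved diagnosis is assigned to the
quarter's middle month, which is unbiased under uniform within-quarter
timing; if that quarter is the death quarter and the middle month falls
after the death month, the diagnosis is clamped to the death month, so the
tie resolves to a death *with* dementia.  Age is completed years from
exact month arithmetic.

**Eligibility.**  A two-year wash-out precedes baseline: persons must be
at least 65 at baseline, continuously covered through the wash-out, and
free of valid diagnoses before baseline.  Follow-up runs three years;
censoring is at death, insurance exit (month after the last covered month)
or the end of the window, whichever comes first.

**Exposure.**  Each person's follow-up is split at their integer-age
boundaries in exact months.  Time before the first valid diagnosis accrues
to the shared DI / non-DM exposure, time after it to DM exposure.
Person-years are conserved exactly (the split is integer-month
arithmetic).  Ages above 100 are pooled into the age-100 cell — whether
the original design capped or pooled is not documented, and pooling loses
no events.  Crude rates carry a normal-approximation Poisson interval,
`rate ± 1.96·1000·√events / PY`, which reproduces published claims-cohort
tables at one decimal.

## Period trends

Counts aggregated by single year of age and period are modelled with an
NB2 negative binomial regression (log link, log person-years offset) with
covariates `(age − c)`, `(age − c)²` and a period dummy; the exponentiated
period coefficient is the adjusted rate ratio.  The centering constant `c`
defaults to the person-years-weighted mean age of the exposed population
and may be overridden (e.g. with published constants such as 73.92 years
for men); the period rate ratio is invariant to this choice, which the
tests verify.  Aggregation by single year of age is itself a choice — the
original analyses may have used person-level records — and it affects
standard errors slightly but not the estimand.  Dispersion is estimated by
maximum likelihood; when the data carry no extra-Poisson variation the
dispersion diverges to zero and the fit is taken at its Poisson limit,
recorded in the result's `notes`.

## Old-age smoothing

Observed rates above age 80 fluctuate; ages 80–100 are therefore replaced
by a Kannisto logistic fit,
`mu(x) = a e^{b(x−80)} / (1 + a e^{b(x−80)})`, estimated by maximum
Poisson likelihood with mean `exposure(x)·mu(x)`.  Choices worth stating:

* *Poisson likelihood, not least squares on logits* — zero-event cells at
  the oldest ages remain informative.
* *Anchoring at age 80* is a pure reparameterisation for numerical
  conditioning.
* *Deterministic start* (`a` at the observed rate at 80 clipped to
  `(1e-6, 0.9)`, `b = 0.1`) plus a small restart grid; convergence is
  declared when the gradient's maximum absolute entry falls below
  `1e-8 · max(1, total events)` — the relative form of a gradient-norm
  rule, since an absolute norm is meaningless across count scales — or
  when a parameter reaches its box bound (the flat-data limit `b → 0` is
  reported in the fit's `note`).
* *All three transitions are smoothed with the same model by default.*
  Whether incidence should share the logistic asymptote of old-age
  mortality is debatable, so `di_model = "gompertz"` switches the
  incidence transition to a log-linear Poisson GLM.

## Bootstrap confidence intervals

Uncertainty is propagated by resampling the age-specific counts of
incident dementia cases and dementia deaths as
`events* ~ Binomial(round(PY), events/round(PY))` — one trial per
person-year, the only trial size the aggregated data offer — and re-running
smoothing, life table and ALE on each replicate; percentile intervals
(default 95%, 1000 replicates) are reported, with the point estimate always
taken from the unresampled data.  Non-dementia deaths are *not* resampled
by default, matching the two series named above; `resample_set` extends
this, and a Poisson resampling variant exists as a sensitivity check.
Replicates whose smoothing fit fails are dropped and counted; more than 5%
failures abort the stratum.  Significance between two intervals is read as
non-overlap — conservative, but the only rule available without a joint
resampling distribution.

The suite checks interval calibration at reduced scale: 200 synthetic
datasets with binomially drawn DI and DM counts at a known truth, 200
replicates each, requiring empirical coverage of the true dementia ALE in
90–99%.  The truth grid there is Gompertz below 80 with an exactly
Kannisto continuation above, so the smoother is correctly specified and
the check isolates the interval rather than smoothing bias.  Binomial
noise in the generating step mirrors the mechanism the data embody: at
dementia-mortality rates of 0.15–0.55 per person-year, at most one death
can occur per person-year trial, and Poisson noise would overstate the
count variance by `1/(1−p)`.

## The synthetic-claims generator

Because the underlying claims data are access-restricted, the package
ships a generator whose defaults emulate the study design: two cohorts
(baselines 2006 and 2016) of 50,000 persons each, a two-year wash-out,
three follow-up years, Gompertz transition hazards with sex-specific
period rate ratios, quarterly diagnosis recording and month-exact deaths.
Default parameter choices, made once:

* entry ages `65 + 35·Beta(1, 3.0)` for men and `Beta(1, 2.3)` for women —
  decreasing densities with means near 74 and 76, the typical mean ages of
  exposed insured populations;
* Gompertz levels and slopes placed so crude rates land in the observed
  ranges (incidence ≈ 20–30, non-dementia mortality ≈ 29–43, dementia
  mortality ≈ 210–290 per 1,000 person-years);
* period rate ratios at the published sex-specific trend estimates
  (incidence 0.927/0.903, dementia mortality 0.880/1.062, non-dementia
  mortality 0.931/0.937 for men/women);
* `record_prob = 0.85` per quarter (claims under-recording is real and
  uncorrectable downstream), isolated unverified false positives at 0.002
  per person-quarter, insurance exit at 0.005 per year (observed switching
  was 1.7% and 0.4% per three-year period).

The false-positive mechanism emits exactly one unverified record per
event, which the two-records rule must reject; a `paired_false_positives`
flag emits same-quarter verified pairs instead, the rule's designed
failure mode, so tests can demonstrate the boundary of what internal
validation can catch.

The generator does **not** emulate: co-morbidity and care-level structure,
diagnosis-seeking behaviour that correlates recording with severity or
proximity to death, secular drift within a period, under-recording that
varies by age or sex, or etiologic subtypes.  Passing recovery tests on
synthetic data therefore shows the *pipeline* is correct under the stated
model, not that the model captures every feature of real claims data.

## Validation studies and problem sizes

The test suite ties each stage to an independent oracle, at sizes chosen
to keep Monte Carlo error well below the tolerances being asserted:

* life-table recursions against closed forms (`1e-12`) and against a
  forward microsimulation of one million agents on five random rate grids
  (agreement within three Monte Carlo standard errors);
* trend recovery: cohorts of 100,000 persons per period simulated with a
  true incidence rate ratio of 0.90, twenty seeds; the 95% Wald interval
  must cover the truth in at least 17;
* validation rules: with full recording, 100% of isolated unverified
  false positives are rejected and at least 99% of onsets with a
  subsequent covered quarter are detected at the correct quarter;
* empirical cohort incidence against a fine-grid numerical integration of
  the configured hazards over the entry-age distribution (three standard
  errors, 50,000 persons).

## Known limitations

* The Markov assumption ignores duration in state: mortality after onset
  depends only on current age, not time since diagnosis.
* No recovery transition exists (dementia is absorbing except for death).
* The period effect in the generator is a single multiplicative shift; no
  within-period trend.
* Under-recording (`record_prob < 1`) biases detected incidence downward
  and is not corrected, only emulated; the period rate ratio is largely
  insensitive to it because the thinning cancels between periods.
* The percentile bootstrap ignores correlation between strata, so
  between-stratum contrasts via non-overlap are conservative.
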