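---
title: "Methods: lifecycle, persistence and proximity analysis of portal access logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifecycle, persistence and proximity analysis of portal access logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portalusage)
```

## The problem

Patient portals for chronic disease — here, a renal portal giving chronic
kidney disease patients live access to their blood results — accumulate an
audit trail: every logon is stamped, and every upload of new laboratory
results is dated. From nothing more than these two event streams plus a
registration date and a fixed census (extraction) date, one can ask: who
never starts, who tries and gives up, who keeps coming back, how long use
endures, and whether logons are driven by the arrival of new results.

`portalusage` implements that analysis as a reusable pipeline over four CSV
tables (patients, centers, logons, results) and validates every stage
against synthetic cohorts with known ground truth.

## Lifecycle classification

Registrants are classified by `classify_cohort()` into five mutually
exclusive classes, applied in strict priority order:

1. **insufficient follow-up** — too little time has passed to judge a
   pattern. Two restrictions are provided, because the two cohort
   definitions in common use differ: the default excludes patients enrolled
   within 6 months of census; the alternative (`first_logon_3m`), used for
   the lapse analyses, restricts to patients whose *first logon* predates
   census by more than 3 months. They are not equivalent and the package
   deliberately implements both rather than presuming one correct.
2. **never logged on** — zero logons.
3. **early lapser** — every logon within the first month (30 exact days,
   day 30 inclusive) after registration.
4. **late lapser** — no logon in the 6 months before census *and* at least
   2 result uploads dated strictly after the last logon. The result
   requirement is a liveness proxy: results keep arriving only for patients
   still alive and monitored, so their silence is a choice, not death or
   discharge.
5. **persistent user** — everyone else.

A patient satisfying both the early and the late rule is an early lapser:
the rules are a priority list, not independent predicates. A "month" in all
interval arithmetic is 30.4375 days (365.25/12); the "first month" gate
alone uses 30 exact days. Both are arguments, not constants. Boundary
conventions (a gap of exactly 6 months counts as lapsed; a result dated the
day of the last logon does not count) are fixed in `classification_params()`
and exercised by boundary tests.

## Persistence of use

`use_durations()` measures use from first to last logon and right-censors
durations consistent with continuing use: last logon within 6 months of
census, or fewer than 2 result uploads after it (follow-up too sparse to
infer abandonment — which also censors patients who used the portal up to
death; no separate death flag exists in the data model). The time origin is
the first logon. `km_estimate()` is the product-limit estimator with
Greenwood variance and log-transformed 95% limits, delegated to
`survival::survfit()`; events precede censorings at tied times.
`attrition_rate()` reads annualized drops off any step curve, including one
assembled from a published series of survival probabilities.

## Activity intensity

`activity_profiles()` computes logons per month under two denominators, both
first-class because both are used in practice: registration-to-census, and
first-to-last-logon (the latter restricted to users with at least three
logons spanning at least 3 months; ineligible patients are excluded, not
errors). The natural logarithm of the rate is quartiled; log base is
immaterial to quartile membership, which is the analyzed quantity.
Quartile assignment is rank-based with stable patient-id tie-breaks, so cut
points sit at the empirical 25/50/75 percentiles, exact-cut values go to the
lower quartile, and the four parts always differ in size by at most one —
even under heavy ties. `top_fraction_flag()` marks the heaviest-using 5%
(ceiling of the fraction), and `time_histograms()` profiles weekday and
hour-of-day use.

## Logon-to-result proximity and its permutation null

For every logon, `pooled_intervals()` finds the signed whole-day interval to
the nearest result (positive = logon after the result; equidistant ties go
positive, since post-result viewing is the object of the analysis; intervals
use calendar dates because results are date-only). `proximity_histogram()`
bins these in 1-day bins over ±28 days by default, with all logons as
denominator, and `headline_fractions()` reports the shares on
`[0,1)`, `[0,3)`, `[-3,0)` and `[0,14)` days.

Significance comes from `shuffle_null()`: per permutation, each patient's
logon dates (or result dates) are redrawn uniformly over whole days within
that patient's own observation window (first logon to census), preserving
per-patient counts and windows exactly. Shuffling *within* patients is a
deliberate choice: pooling events across patients would destroy per-patient
rate heterogeneity and overstate significance. Per-bin p-values use the
add-one estimator `(1 + #{null >= obs}) / (1 + B)`, so the smallest
attainable p with 999 permutations is 0.001.

## Factor associations

The three participation "hurdles" — never completing a first logon, lapsing
early, lapsing late — are modelled by `fit_factor_model()` as logistic
regressions (via `stats::glm`) of the hurdle outcome on age band, gender,
treatment, deprivation group and center covariates (assisted start,
offering under 2 years, registration-rate quartile). Reference levels
default to age 35–54, hospital haemodialysis and middle deprivation. The
late-lapse cohort is late lapsers versus persistent users, excluding early
lapsers. `eliminate_factors()` performs backward elimination: the factor
whose removal yields the largest likelihood-ratio p-value is dropped, whole,
while that p-value exceeds `alpha` (default 0.05 — a conventional choice;
the procedure, not the threshold, is the substance), stopping when all
remaining factors are significant. `compare_to_reference()` contrasts
registered counts against an external population by Pearson chi-square.

Separation and aliasing are reported as errors naming the offending terms
rather than silently returning enormous intervals.

## The synthetic cohort generator

`generate_cohort()` is not a test fixture but a first-class model of the
data-generating process the analysis assumes:

* **Covariates** are drawn from configurable frequencies; defaults mirror a
  registered renal-portal population (e.g. 37.9% aged 35–54, 59.9% male,
  19.4% hospital haemodialysis, 41.1% not yet on renal replacement
  therapy).
* **Result schedules** are uniform-interval renewal processes: 21–39 days
  for hospital haemodialysis (monthly monitoring), 90–365 days otherwise
  (the 3–12-monthly testing typical of CKD and stable transplants).
* **Logon streams** are superpositions of piecewise-constant-intensity
  Poisson components — baseline, an early post-registration burst, an
  excess window after each result, and a small bump before each result —
  scaled by a log-normal per-patient multiplier (mean 1) that produces the
  wide per-patient rate range seen in real logs (two orders of magnitude).
  Piecewise-constant intensities make superposition exact, so no thinning
  is needed.
* **Lifecycle classes** are drawn from a mixture (defaults follow the
  observed cohort flow: 23.2% never, 7.2% early, 12.4% late, the rest
  persistent), optionally re-weighted at assisted-start centers
  (default weight 0.31 on never-logging-on). The class shapes the stream:
  early lapsers' logons stay within 25 days of registration, late lapsers
  stop at a true stop date drawn from an exponential per-month hazard
  (truncated to keep at least 2 results and ~7.4 months between stop and
  census), persistent users run to census with a guaranteed recent logon.
  Margins are generated strictly inside the rule boundaries so that the
  classifier should recover the labels; recovery is itself a test.
* **Time of day** is drawn from a 08:00–22:00-weighted profile.

Ground truth (class and stop date) is returned as a separate table so that
pipeline inputs never leak labels. Identical config and seed give
byte-identical CSV output.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: weekday/holiday structure, shared family logons,
re-registration, result *values*, and any drift of behaviour over calendar
time. Recovery tests demonstrate that the pipeline is correct under its own
assumptions, not that real cohorts satisfy them.

## Deterministic fixtures

Two constructed, fully deterministic datasets pin the cohort-flow
arithmetic end to end: `make_printed_cohort_fixture()` (11,352 registrants
of whom 2,634 never log on, 469 first log on within 3 months of census, and
the remaining 8,249 split 822 / 1,404 / 6,023 into early lapsers, late
lapsers and persistent users) and `make_activity_fixture()` (5,808 users
with ≥3 logons over ≥3 months, 5,085 persistent and 723 late-lapsing).
The late-lapse count is the arithmetic remainder 1,404; a conflicting count
of 1,401 appears in some tabulations of the same cohort and is left
unreconciled rather than silently adjusted. Covariates in these fixtures
are cyclic filler: they pin classification counts, not associations.

## Numerical and design choices

* Exactly-on-boundary behaviour is fixed and tested: day 30 is "first
  month"; a 6.0-month gap is lapsed; an exact 75.0 years is in the 55–74
  band (the bands are labelled "55–74" and "over 75").
* Degenerate inputs: empty cohorts tally to zero counts; patients without
  logons are excluded from duration and activity analyses rather than
  crashing them; all-censored inputs give a flat survival curve at 1.
* The KM confidence band is clamped to `[0, S]`/`[S, 1]` endpoints where
  the log-transformed interval is undefined (S = 0, or no variance
  accrued).
* Elimination is deterministic: ties in LRT p-values resolve to the first
  factor in model order via `which.max`.

## Problem sizes used in the validation suite

The test suite sizes simulations to keep the full run in minutes while
leaving Monte-Carlo error well inside the asserted tolerances: label
recovery on 5,000 patients (99% threshold), hazard recovery on 2,000
lapsing users (3 standard errors, read off the KM curve 3 months into
follow-up), odds-ratio recovery and 200-replicate CI coverage at n = 5,000,
permutation calibration over 20 replicate null cohorts of 200 patients with
199 permutations each, and a 999-permutation power check on a strongly
coupled cohort of 300. Oracle checks run exhaustively where cheap (all
2×2 tables with cells up to 6) and by random sampling above that.

## Limitations

The pipeline takes deprivation deciles, treatment and center attributes as
given inputs; it does not resolve postcodes, model center random effects,
fit smooth (additive) age effects, or treat death as a competing risk — the
censoring proxy absorbs it. The two cohort-restriction conventions and the
two activity denominators are reported explicitly wherever they change a
number.
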