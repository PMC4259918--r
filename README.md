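# portalusage

Quantitative analysis of patient-portal audit logs for chronic-disease
cohorts, built for registries like a national renal portal where patients
view their own blood results online. From four plain CSV tables — patients,
centers, logon events, result-upload events — plus a census date, the
package answers the questions such a log can support:

* **Lifecycle classification.** Every registrant is assigned one of five
  classes by rules applied in priority order: insufficient follow-up,
  never logged on, early lapser (all logons within the first 30 days after
  registration), late lapser (no logon for ≥ 6 months before census with
  ≥ 2 result uploads after the last logon — a liveness proxy), or
  persistent user.
* **Persistence of use.** Use runs from first to last logon; durations are
  right-censored when the last logon is within 6 months of census or is
  followed by fewer than 2 results. Survival of continuing use is the
  Kaplan–Meier product-limit estimator S(t) with Greenwood 95% limits,
  overall or by factor, plus annualized attrition between any two points of
  the curve.
* **Activity intensity.** Logons per month under two denominators
  (registration→census, or first→last logon for users with ≥ 3 logons over
  ≥ 3 months), quartiled on log(logons/month), top-5% flagging, and
  weekday/hour-of-day histograms.
* **Logon-to-result proximity.** For each logon, the signed whole-day
  interval to the nearest result (positive = after the result), pooled into
  a 1-day-bin histogram, with headline shares (same day, 0–3 days after,
  3 days before, within 2 weeks) and a per-patient shuffling permutation
  null with 95% envelopes and add-one p-values
  p = (1 + #{null ≥ obs}) / (1 + B).
* **Factor associations.** Logistic models (odds ratios with Wald 95% CIs)
  of the three participation hurdles — not completing first logon, early
  lapse, late lapse — with backward elimination by likelihood-ratio test,
  and Pearson chi-square comparison of registration proportions against a
  reference population.
* **Synthetic cohorts.** A generator with ground-truth labels: mixture of
  lifecycle classes, treatment-dependent result schedules (monthly for
  hospital haemodialysis, 3–12-monthly otherwise), and logon streams as
  superposed piecewise-constant Poisson processes (baseline, initial burst,
  post-result excess, pre-result bump, log-normal per-patient rates). Two
  deterministic fixtures reproduce the published cohort-flow arithmetic of
  an 11,352-registrant registry exactly.

## Worked example

```r
library(portalusage)
census <- as.Date("2009-09-07")

g <- generate_cohort(generator_config(n_patients = 2000, seed = 42))

cl <- classify_cohort(g$patients, g$logons, g$results, census)
class_counts(cl)
#>   usage_class                n   pct pct_classified
#> 1 insufficient_follow_up     0  0             NA
#> 2 never_logged_on          436 21.8           21.8
#> 3 early_lapser             141  7.05           7.05
#> 4 late_lapser              240 12             12
#> 5 persistent_user         1183 59.2           59.2
```

About a fifth of registrants never log on and most of the rest persist —
the class mixture the generator plants by default. Survival of use and
proximity to results:

```r
du <- use_durations(g$patients, g$logons, g$results, census)
km <- km_estimate(du)
km$survival[max(which(km$time <= 6))]
#> [1] 0.885     # probability of still using the portal 6 months after first logon

round(unlist(headline_fractions(pooled_intervals(g$logons, g$results))), 3)
#> frac_after_0_1 frac_after_0_3     frac_pre_3 frac_within_14
#>          0.093          0.280          0.078          0.346

sn <- shuffle_null(g$logons, g$results, census, n_permutations = 999, seed = 1)
sn$bins[sn$bins$bin_start %in% 0:2, c("bin_start", "proportion", "null_mean", "p")]
#>   bin_start proportion null_mean     p
#> 1         0     0.0927    0.0144 0.001
#> 2         1     0.0938    0.0144 0.001
#> 3         2     0.0927    0.0144 0.001
```

28% of logons fall in the three days after a result upload — six times the
shuffled-times expectation, rejected at the smallest attainable p
(0.001 with 999 permutations): logons cluster on fresh results.

A thin CLI over the same functions lives at `inst/cli/portalusage.R`
(subcommands `simulate`, `classify`, `activity`, `survival`, `proximity`,
`associate`).

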