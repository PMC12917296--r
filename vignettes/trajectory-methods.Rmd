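---
title: "Adherence and drug-pattern trajectories from dispensing records: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adherence and drug-pattern trajectories from dispensing records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxtraject)
```

This vignette is the package's account of its methods: the measurement model
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where the methodology was genuinely open.

## The measurement problem

Pharmacy dispensing data contain one row per dispensing event: patient, date,
ATC drug code, strength, units, and days of supply. Everything else —
exposure episodes, adherence, treatment changes — must be *reconstructed*
from the timing and supply arithmetic of those rows. The package follows the
conventions of new-user (inception) cohort designs in lipid-lowering
pharmacoepidemiology: cohort entry at the first-ever dispensing of a study
drug, a clean lookback window, and outcomes defined over fixed 360-day years
(180 days ≈ half a year, 3,600–3,780 days ≈ ten years). All intervals are
half-open `[start, end)` and handled internally as integer day offsets from
the index date.

## Cohort construction

A patient becomes a cohort entry when six rules hold, applied in order (the
attrition table records each step): a study-class dispensing exists; exactly
one study class is initiated on the index day (same-day initiation of two
classes is not monotherapy — excluded); age at index is at least 18
(`min_age`, configurable; "older than 18" and "aged 18 and older" are both in
circulation for this design, and the inclusive reading is the default);
at least `history_days = 720` days of database records precede the index and
`post_days = 360` follow it; and at least `min_fills_year1 = 3` index-class
dispensings fall in the first year. Database *presence* is operationalised as
first/last dispensing of any drug — dispensing-only databases carry no
registration dates, so the first recorded dispensing is the best available
anchor.

Exclusions then remove patients with antihypertensive or fixed-dose
combination dispensings in `[index, index + 360)` and patients with
dispensings from a cardiac drug list in `[index − 720, index + 90)`. The
shipped cardiac list (C01 cardiac therapy, B01 antithrombotics) is a
*reconstruction* of the usual dispensing-data proxy for acute/possible
chronic cardiac disease; protocols with an exact list should override
`atc_vocabulary()$exclusion_map$cardiac`.

Follow-up ends at the earliest of: the administrative study end (2020-12-31)
capped at `index + 3780` days; the first cardiac-proxy dispensing
(`cv_event_proxy`, **off** by default — dispensing databases carry no
diagnoses, so this proxy is opt-in); the supply runout of the final
index-class dispensing; or the first switch/add-on date. Ties resolve in
that order.

## Coverage and adherence

Each dispensing contributes `days_supplied` covered days. A refill dispensed
before the previous supply runs out starts at the previous runout
(carryover); the carried stockpile is capped at `stockpile_cap_days = 90`.
The cap matters: pure truncation (`cap = 0`) systematically undercounts
covered days for early refillers, while unlimited carryover lets a patient
bank arbitrary supply. Ninety days — one typical maximum dispensing length —
is the default compromise, and both extremes remain available. The interval
implementation is verified in the test suite against a literal day-by-day
pill-supply simulation.

Yearly adherence is covered days within the 360-day year divided by 360 — a
proportion-of-days-covered metric with a fixed denominator. Because covered
days are a set of calendar days, a year's value cannot exceed 1; surplus
supply is carried into later years rather than inflating the current one.
The high/low cut is 0.8, **inclusive** on high. A patient contributes year
*k* only while persisting on the original monotherapy beyond `k × 360` days
(no discontinuation, switch or add-on event earlier); patients outside the
risk window are excluded from that year's denominator, not counted as zero.
This persister denominator is the reading most consistent with
prevalence-by-year reporting over ten years.

The 3-year window variant divides covered days during follow-up by the
individual follow-up time, among patients whose records span more than
3 years while their time on the original monotherapy is at most 3 years.

## Pattern classification

Patterns are assessed against the observation cap `min(study_end,
index + 3780)` rather than the pattern-dependent follow-up end — the
follow-up end is *derived from* the pattern dates, so using it as the
assessment horizon would make discontinuation undetectable by construction.

* **Discontinuation**: a supply gap strictly greater than 180 days, measured
  from a coverage runout to the next index-class dispensing (or to the
  horizon). The gap is measured from runout because "stopping" means
  exhausting supply, not ceasing to visit the pharmacy; a
  last-dispensing-date convention is available (`gap_from_runout = FALSE`).
* **Switch**: a different study class or fixed-dose combination dispensed
  within 180 days *after* the discontinuation runout, inclusive of day 180.
  Switch therefore implies discontinuation.
* **Add-on**: a second class dispensed while index coverage is active —
  strictly inside a coverage interval — and before any discontinuation.
  "Before discontinuation" alone is ambiguous during short mid-therapy gaps;
  the strict-coverage reading is the default and the permissive one is a
  switch (`addon_requires_coverage = FALSE`).
* **Continuation**: an eligible patient with none of the above. Dose changes
  of the same compound do not break continuation; dose-level movements are
  the equivalent-dose module's job.

Flags are non-exclusive except where logic forbids: a patient may add on and
later discontinue; continuation excludes everything else; switch implies
discontinuation. These implications are asserted as invariants in the tests,
and the whole classifier is checked against an independent day-level scan on
randomized trajectories. Counts are tabulated per index class as `n (p%)`
with one-decimal percentages among patients persisting beyond one year.
Whether switch/add-on tabulations should count only first events is an open
reporting question; the package counts any event during follow-up.

## Equivalent-dose tiers

Daily dose is `strength_mg × units / days_supplied`; records missing
strength or units are excluded from dose analyses with a logged count. Doses
map to three tiers aligned with expected LDL-cholesterol reduction bands
(< 30%, 30–45%, > 45%). The shipped cut-offs follow standard
statin-intensity banding (e.g., simvastatin 10 = low, 20–40 = medium;
atorvastatin 10–20 = medium, 40–80 = high; rosuvastatin 5–10 = medium,
20–40 = high) and are explicitly a reconstruction — no authoritative dose
table ships with dispensing data — so the table is fully overridable and
validated for non-overlap and monotonicity. Doses above a class's highest
band extend monotonely to `high`, below the lowest to `low`, and gaps
resolve to the nearest boundary (ties to the lower tier). Fibrates have no
LDL-equivalence and collapse to a single tier.

## The statistical layer

Logistic risk-prediction models use maximum likelihood with Wald 95%
intervals (the conventional reporting scale; profile intervals would differ
only in small strata). Reference levels are fixed: simvastatin, low
adherence, female, age 18–39, comorbidity absent, calendar 1996–2000. The
7:3 train/test split is seeded and exhaustive. AUC is pairwise concordance
with ties counting one half; sensitivity and specificity are reported at a
0.5 probability cutoff by default — with prevalent outcomes most predicted
risks sit on one side of 0.5, so these can be near-degenerate (1 and 0);
the cutoff is a parameter precisely because this convention matters.
Hosmer–Lemeshow uses 10 quantile groups (ties kept together, sparse groups
flagged), statistic `Σ (O − E)² / (E(1 − E/n_g))` on `g − 2` degrees of
freedom. The Lasso variant standardises the dummy-coded design, picks the
penalty by 10-fold cross-validated deviance with seeded folds, and refits
the selected covariates unpenalised for interpretable odds ratios.

For the 3-year transition analysis, everyone enters in the low-adherence
state and the event is the transition to high adherence. The transition time
is the end of the first 360-day year with adherence ≥ 0.8 — yearly adherence
is the measurement unit, so the year boundary is the finest honest event
time; finer constructions would pretend to precision the metric lacks.
Kaplan–Meier curves are stratified by treatment class. Treatment effects are
estimated by Cox regression weighted with stabilised
inverse-probability-of-treatment weights from a multinomial-logistic
propensity model (marginal class probability over fitted conditional
probability, truncated at the 1st/99th percentiles), robust sandwich
variance, and — optionally — treatment-by-log(time) interactions as the
operationalisation of time-dependent effects, with a Schoenfeld-residual
diagnostic attached. Classes with fewer than 25 subjects are flagged;
classes with no events report `NA` hazard ratios.

## The synthetic generator: what it emulates, and what it does not

`generate_population()` simulates the study conditions: new users of the six
classes over 1996–2020 with a simvastatin-dominated class mix, ages from a
truncated normal (mean 58, SD 12, range 18–90) so that all three age bands
are populated, equal sexes, and independent Bernoulli baseline co-medication
flags realised as dispensing rows in the first 180 days (diabetes
prevalence 0.20, the others 0.005–0.10).

Two independent latent dimensions drive each trajectory:

* **Adherence.** A logistic model with planted odds ratios — male 0.79, age
  40–69 1.68, age ≥ 70 2.46, diabetes 1.17 — draws a binary high/low
  adherence label. The intercept default (1.19 logit) was solved
  numerically so the marginal year-1 prevalence of high adherence under the
  default covariate mix is 0.836. The label is realised by *thinning
  refills*: high adherers refill every 30 ± 3 days, low adherers every
  46 ± 3 days, with 30-day supplies, which pins year-1 adherence to
  ≥ 0.917 versus ≤ 0.75. The deterministic separation around the 0.8 cut is
  deliberate: the emitted label and the downstream classification agree
  exactly, so planted odds ratios are recovered without misclassification
  attenuation — the Monte-Carlo error of the Bernoulli draw is the only
  noise. Supply counts stay realistic because the supply field is never
  shortened, only the refill timing.
* **Archetype.** Each patient is a continuer, discontinuer, switcher,
  add-on user, or intermittent user (default mix 0.30 / 0.32 / 0.18 / 0.12 /
  0.08, chosen to land near realistic pattern rates). Discontinuers stop
  after their first runout past day 366 (plus 0–2 extra fills); switchers
  additionally receive another class 100–166 days after the naive runout —
  past any possible 90-day stockpile extension, yet within the 180-day
  switch window of the true runout; add-on users receive a second class on
  an index refill day (guaranteeing active coverage) between days 367 and
  649; intermittent users get one 60–110-day refill hole after year 1
  (short enough never to count as discontinuation). Index dates leave at
  least 780 days before the study end so every archetype's defining event
  is observable; anchor dispensings of a non-study analgesic establish the
  required database presence before and after index. Ground truth goes to a
  separate labels table that the analysis tables never see.

What the generator does **not** emulate: seasonal or prescriber effects,
correlated comorbidities, dose titration within a compound, hospital
dispensing gaps, mortality and emigration, or re-initiation after
discontinuation. Passing tests therefore demonstrate that the *measurement
and modelling machinery* is correct under known ground truth — not that any
particular real-world database would show these rates.

## Numerical and scale choices

Tests and the acceptance script run the full pipeline at n = 50,000 for
parameter recovery (a few minutes on one core) and n ≤ 5,000 elsewhere;
oracle equivalence uses hundreds of randomized traces. Coverage
construction is evaluated position-wise across patients, so its cost scales
with the maximum refill count rather than the cohort size. Determinism is
end-to-end: one seed fixes the generator byte-for-byte, and split/fold/weight
computations each take explicit seeds.

## Known limitations

The package deliberately stops short of: restart/re-initiation episodes
after a switch, therapy-episode chains beyond the first pattern event,
dose-based (DDD) adherence, clinical endpoint ascertainment, and any
multiplicity control across the five outcome models (none is applied;
p-values are reported as-is). The fixed-combination and cardiac ATC lists
and the EQD dose table are documented reconstructions intended to be
overridden by protocol-specific configuration.
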