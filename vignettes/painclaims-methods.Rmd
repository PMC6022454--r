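---
title: "Methods: claims-based chronic-pain phenotyping and prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based chronic-pain phenotyping and prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painclaims)
```

## The problem

Administrative claims databases cover an insured population's diagnoses
(medical claims with ICD-9 codes) and dispensings (pharmacy claims with a
drug identifier and a days' supply). Chronic pain leaves no single code, so
cohorts must be phenotyped with a rule set. `painclaims` implements a
two-criterion, per-person-per-calendar-year definition:

* **Diagnosis criterion.** One claim bearing a *highly likely* chronic-pain
  code (the 338 family, cancer pain carved out), or two claims bearing
  *likely* codes on service dates separated by at least 30 days within the
  year. Person-years carrying only migraine/other-headache/facial-pain or
  cancer-pain (338.3x) codes, with no qualifying include pattern, are
  excluded; an include pattern always wins over the exclusion.
* **Opioid criterion.** At least 90 consecutive days of opioid coverage
  within the calendar year, where each fill covers
  `[fill date, fill date + days' supply − 1]`.

A cohort record carries both flags and a three-way classification
(`icd_only` / `both` / `opioid_only`), which partitions each year's cohort.

## Interpretation choices in the case definition

Several points of the verbal definition are under-determined; the package
fixes them as follows, and exposes each as a `finder_policy()` parameter
where reasonable people could differ.

* **"One diagnosis per calendar year"** for the 338 family is read as *at
  least one*. Reading it as *exactly one* would make an additional
  confirmatory diagnosis remove a person from the cohort, which has no
  clinical rationale.
* **"Daily use"** of opioids is operationalized as days of coverage from
  fill date plus days' supply — the standard pharmacoepidemiologic
  construction, since claims record dispensing, not ingestion. Two overlap
  policies are provided: `union` (default; overlapping fills' days count
  once — conservative) and `stockpile` (an early same-drug refill is
  shifted to start the day after the previous fill's coverage ends).
  Stockpiling is applied per drug: concurrent prescriptions for different
  opioids are plausibly taken in parallel, not banked.
* **Calendar-year clipping.** Coverage runs are merged first, then clipped
  to January 1–December 31 before the 90-day test (`clip_to_year = TRUE`).
  A run of 50 December days plus 50 January days therefore qualifies in
  *neither* year. This is the strict reading of "within the calendar year";
  the permissive alternative (a qualifying run credits every year it
  touches) is available with `clip_to_year = FALSE`.
* **Grace gap.** `grace_gap_days` (default 0, i.e. strictly consecutive)
  merges coverage intervals separated by at most that many uncovered days;
  the merged run includes the gap days. Real dispensing has small refill
  gaps, so analysts commonly allow 1–7 days; the default stays strict
  because the definition says "consecutive".
* **Diagnosis-pair separation** uses the extreme service dates across all
  likely-code claims in the year (equivalent to the best pair), with an
  at-least-30-days comparator, so Jan 10 + Feb 9 qualifies.
* **ICD-9 matching** strips dots and upper-cases before prefix matching
  (extracts vary in dot usage), and the most specific configured prefix
  wins — which is precisely how 338.3x (cancer pain) is carved out of the
  338 include family.
* The shipped *likely* code list and opioid drug list are documented
  synthetic stand-ins: the validated lists of the source phenotyping
  algorithm are not reproduced here. Both are plain arguments
  (`code_config()`, `opioid_list()`) and can be loaded from YAML/JSON with
  `read_finder_config()`; all results depend on them.

## Prevalence, payer attribution and tests

Prevalence is `100 · cases / population` per stratum, with numerators from
cohort records and denominators from a census table (county × sex ×
five-year age band, plus county covariates). Age is `analysis year − birth
year` — claims extracts rarely carry full dates of birth — and bands run
`<5, 5–9, …, 80–84, 85+`. Note one definitional caveat inherited from the
study design: with a real census denominator and a claims-derived (insured)
numerator the ratio is not a true proportion of the insured population, and
elderly strata can exceed 50%; the package computes the definition as
stated. On synthetic data the emitted census holds the *realized* stratum
counts, so this mismatch does not arise and recovery is exact.

Payer type is recorded per claim (insurance is attributed to the claim that
paid, not to the person); the person-year label is the majority payer over
its pooled medical and pharmacy claims, with exact ties going to `public`.
The tie-break is documented rather than principled — the data cannot
distinguish it.

The significance procedures are the classical ones: a pooled-variance
two-sample z for differences of proportions (no continuity correction), a
one-sample z for a proportion, and the t test for a Pearson correlation on
n − 2 degrees of freedom. All are two-sided; no multiple-testing adjustment
is applied (matching standard practice for these descriptive comparisons),
and `county_correlations()` reports how many tests it ran implicitly via
one row per covariate. Correlations are computed on raw values, so a
"positive association with *lower* income" appears as a negative r between
income and the public-insurance share. Degenerate inputs are handled
explicitly: a pooled proportion of 0 or 1 yields statistic 0 with a
warning; |r| = 1 yields p = 0 with a warning; constant series are contract
errors.

## The synthetic-data generator

`simulate_claims()` emulates the structure of a multi-year all-payer
extract: persons drawn i.i.d. from age/sex/county marginals (an old-state
age pyramid, 51.3% female, 16 Maine-like counties with plausible — not
census-extracted — population weights, incomes, poverty and education
levels), per-person medical and pharmacy claim streams, income-linked
public-payer probability per county, and planted chronic-pain status at a
29.5% per-person-year target with a case mix of 84% diagnosis-only, 13%
both routes, 3% opioid-only — the regime reported for this phenotype (a
diagnosis-dominated cohort with an opioid-criterion share in the
15–19% range).

Design points that matter for testing:

* **Label soundness by construction.** Every planted pattern provably
  satisfies or fails the criteria: diagnosis routes get one highly-likely
  claim or a likely pair ≥ 30 days apart; opioid routes get fill chains
  realizing 90–150 contiguous covered days within the year; non-cases get
  *at most one* near-miss noise pattern — a single likely diagnosis, a
  likely pair 1–29 days apart, an opioid run of 60–89 days, or
  headache-only diagnoses — so patterns can never combine across draws into
  an accidental qualifying pattern. Near-miss noise is always on by
  default: the hard parts of the criteria are the temporal boundaries, and
  the noise keeps them permanently exercised.
* **Realized census.** The census table is emitted from realized stratum
  counts, not the target marginals, so prevalence recovery is exact rather
  than approximate, and stratum counts sum to `n_persons` by construction.
* **Birth-year consistency.** A person aged *a* at the reference year is
  "born" in `reference_year − a`; in analysis years before birth they
  generate no claims and are labelled non-cases.
* **Overlapping fills.** With `overlapping_fills = TRUE`, planted runs use
  early same-drug refills whose coverage qualifies (cases) or fails
  (noise, total supply ≤ 89 days) under *both* overlap policies, so truth
  labels remain valid whichever policy the finder applies.
* **Determinism.** Each generation stage re-derives its RNG state from
  `sim_config(seed=)`, so populations, claims and written CSV files are
  bit-reproducible for a given configuration.

What the generator does **not** emulate: disease progression or persistence
across years (case status is drawn independently per person-year), comorbid
code correlation, sex- or age-dependent prevalence (uniform by default;
tests that need a sex effect plant it at the label level), claim pricing,
insurer churn within a year, and resubmitted/duplicate claims. Passing
planted-truth recovery therefore demonstrates that the finder implements
the rules exactly — not that the rules are valid on real claims, where
coding practice, data corruption and eligibility churn add error a
synthetic benchmark cannot capture.

## Numerical and validation choices

Interval arithmetic is done in whole days on closed intervals; intervals
with an uncovered gap of at most the grace allowance are merged by a single
sorted sweep. The test suite checks this engine against an independent
brute-force oracle — a boolean day grid for `union`, a day-by-day per-drug
supply-bank simulation for `stockpile` — on 1,000+ fuzzed fill sets (up to
40 fills of up to 120 days' supply, grace gaps 0–7), and the closed-form z
and t statistics against `prop.test(correct = FALSE)` and `cor.test()` to
1e-10 on hundreds of fuzzed inputs.

Validation problem sizes were chosen to make binomial tolerances tight at
desk scale while keeping the full suite under a minute: planted-truth
recovery on 5,000 persons × 4 years (20,000 person-years, zero discordance
required, in both case status and route), type-I error of the two-sample z
over 2,000 null replicates at n = 200 per arm (accepted at 0.05 ± 0.015),
and recovery of a planted county-income association on 16 counties in
≥ 95% of 500 replicates. The published yearly cohort arithmetic (annual
average 330,054 of 1,119,509, i.e. 29.5%; opioid-criterion shares
15.8/16.5/16.5/18.8%) is reproduced exactly from the printed counts, which
function as inputs; the full population-scale tables cannot be reproduced
without the non-public source database.

## Known limitations

* Identification is strictly within calendar years; multi-year episodes
  are out of scope, as are severity grading and morphine-equivalent dosing.
* The default code and drug lists are stand-ins and must be replaced for
  any substantive analysis.
* Prevalence uses raw census denominators (no age-standardization, no
  correction for the uninsured, who are absent from claims data).
* The county-level correlation analysis is ecological; it supports no
  individual-level inference.
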