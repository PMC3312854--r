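---
title: "Evaluating albumin-adjusted free phenytoin against measured concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating albumin-adjusted free phenytoin against measured concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phtadjust)
```

## The clinical problem

Phenytoin is an anti-epileptic with nonlinear pharmacokinetics and heavy
plasma-protein binding; only the unbound ("free") fraction is
pharmacologically active. Routine therapeutic drug monitoring measures the
*total* concentration (therapeutic range 10–20 mg/L) because the free assay
(range 1–2 mg/L) needs an extra ultrafiltration step and is slower and more
expensive. Under normal binding about 10% of the drug is free, so total/10
approximates the free level. Hypoalbuminemia breaks that approximation: with
less albumin to bind to, the free fraction rises and a "therapeutic" total can
hide a toxic free concentration.

The classical repair is the albumin correction (the Sheiner–Tozer equation):

$$C_{adj,free} \;=\; \frac{C_{total} \,/\, (0.2\,\mathrm{Alb} + 0.1)}{10},$$

with phenytoin in mg/L and albumin in g/dL. At the reference albumin of
4.5 g/dL the denominator is exactly 1 and the correction collapses to
total/10. `phtadjust` implements this correction together with everything
needed to *evaluate* it against directly measured free phenytoin in a
monitoring cohort: lab-event linkage, therapeutic-range classification,
concordance tables, method-agreement statistics, and a synthetic cohort
generator so the entire pipeline is testable without patient-level data.

Algebraically the correction assumes a free fraction

$$f_u(\mathrm{Alb}) = \frac{0.1}{0.2\,\mathrm{Alb} + 0.1},$$

available as `implied_free_fraction()`; it equals 0.1 at albumin 4.5 and
rises toward 1 as albumin falls. The three coefficients (0.2, 0.1, divisor
10) are configurable through `adjustment_coefficients()` but default-locked;
renal-failure or pediatric variants are deliberately out of scope, and the
same coefficients are applied at all ages, as is conventional even though
infants' binding may differ.

## Classification and its boundary convention

`classify()` maps a concentration to `L` (below), `T` (within), or `H`
(above) a `therapeutic_range()`. The published ranges do not state whether an
endpoint value such as 20.0 mg/L is "within" range, so the package adopts the
closed interval $[low, high]$: a result exactly at a published edge is
within range. This avoids calling a value out of range when a clinician
reading the printed range would not. Because the total range (10–20) is
exactly ten times the free range (1–2), `classify(scale_total(t), free)` and
`classify(t, total)` always agree — a property the tests exercise.

## Record linkage

`link_observations()` encodes the assembly rules of a retrospective lab
extract:

* Total and free phenytoin form a pair only when their timestamps are
  identical — the same blood draw. Near-misses (a day apart) are not pairs.
* Each pair joins to the **most recent** albumin in a 7-day *lookback*:
  `draw − 7 days ≤ t_albumin ≤ draw`. An albumin drawn after the phenytoin is
  never used, and a same-timestamp albumin is eligible with lag 0.
* `lag_days` is the floored day difference, giving the eight bins 0–7 used in
  the lag subgroup analysis.
* Pairs with no eligible albumin are dropped and counted; the linkage log
  records pairs formed, linked, dropped, plus deterministic resolutions of
  degenerate input: duplicate same-draw phenytoin results keep the *first* in
  input order, while ties among equally recent albumins keep the *last*. The
  data model is silent on both, so the package picks a rule, applies it
  deterministically, and warns.

Albumin units are g/dL by contract; `read_lab_events()` converts g/L by
dividing by 10 using the explicit unit tag only — never by guessing from the
magnitude, since a tenfold unit error inverts the clinical decision.

`first_per_patient()` (idempotent, earliest draw, input-order tie-break)
produces the between-patient analysis set; `consecutive_pairs()` yields the
within-patient adjacent pairs for the stability analysis, always numbering
observations minus patients.

## Concordance and method comparison

`build_table()` cross-tabulates comparator versus reference categories into a
3×3 table. With the ordinal ordering L < T < H, `summarize_table()` splits
mass into *concordant* (diagonal), *under* (comparator ordinally below the
reference — acting on it would push the dose up), and *over*; the three
percentages sum to 100 before rounding, and rounding to one decimal happens
only at the reporting layer.

Two methods are compared with Fisher's exact test on the 2×2 of
concordant/discordant counts per method (`compare_methods()`), the
convention in this literature even though the samples are paired; the
chi-squared test and McNemar's paired test are reported alongside so the
better-specified alternative is always visible. The two-sided Fisher p-value
uses the "sum of tables no more probable than observed" rule; other
definitions exist, which is why the tests pin it against an exhaustive
hypergeometric enumeration for every table with N ≤ 30.

## Continuous agreement

`pearson_r()`, `ols_fit()` (t-based 95% intervals on n−2 df),
`slope_test()` (identity-line test; the α = 0.05 decision provably matches
"1 outside the 95% CI"), `bland_altman()` (bias ± 1.96 SD), and
`diff_vs_covariate()` cover the continuous analyses. Group structure is
tested with `group_anova()` and `unpaired_t()`. Choices worth stating:

* **Percent-bias denominator** is the pairwise mean (x+y)/2, standard
  Bland–Altman practice.
* **Pooled-variance (Student) t** is the default, matching the era's
  statistics packages; Welch is available by flag.
* **No multiple-testing correction** is applied anywhere; every p-value is
  labelled unadjusted in the report.
* Exact fits (zero residual variance) are legal inputs: `ols_fit()`
  suppresses the "perfect fit" note, and `slope_test()` treats a slope
  standard error below `1e-12 · max(1, |slope|)` as exactly zero, returning
  p = 1 when the slope equals the null and p = 0 otherwise.
* All-datapoints regressions pool repeated measures per patient without a
  clustering correction, reproducing the naive analysis such cohorts report;
  the report labels each table with its variant (`first` vs `all`).

## The synthetic cohort generator

No patient-level data accompany this problem, so `generate_cohort()` makes
the statistical structure of such a cohort explicit and samplable. Defaults
(`default_config()`) encode the reference population's *marginals*: 756
patients, 422 male; six location strata dominated by adult inpatients
(weights 535/29/147/10/8/23 over adult inpatient, pediatric inpatient, ICU,
emergency, primary care, other outpatient — the tabulated strata sum to 752
because four patients carry no location, so weights are proportional);
six age bands (20/35/57/334/246/64 from infancy to ≥80 years, uniform within
band); 371/756 on phenytoin monotherapy with 305/67/13 on 1/2/3+ additional
anti-epileptics; 263/756 with a seizure within 24 h; albumin-lag weights
proportional to the observed 0–7-day counts (559, 290, 215, 190, 152, 103,
112, 132); and 997/756 expected repeat draws per patient, realized as a fixed
total of 997 extra draws allocated multinomially so the default cohort always
holds exactly 1753 observations and 997 consecutive pairs.

The generative model per patient: location-dependent true albumin
`Normal(mean_by_location, 0.55)` truncated to (1, 6) g/dL, with means of
3.1/3.4/2.7/3.8/4.2/4.0 g/dL across the six strata — hypoalbuminemia
concentrated in ICU and inpatient settings, normal albumin in primary care —
chosen as physiologically typical values since the source tabulations give
none; binding multiplier `η ~ Normal(0, 0.25)` on the log free fraction,
`f_u = min(1, 0.1·e^η / (0.2·Alb + 0.1))`; true total phenytoin
`LogNormal(log 12, 0.45)` (median 12 mg/L, spanning sub- to supra-therapeutic
categories); free = f_u · total. Measured values add independent
multiplicative assay noise `(1 + CV·z)` with all CVs defaulting to 0.08, a
typical immunoassay imprecision. Repeat draws multiply the total by a
lognormal dose-drift factor (SD 0.35), standing in for the dose changes that
keep real consecutive measurements only ~50% stable in category. Successive
draws are at least eight days apart so each pair has exactly one eligible
albumin — a simplification that makes the linkage conservation property
exact.

Because the generative free fraction is the correction's own algebra in
expectation, the adjustment is the *correctly specified* estimator here:
with `binding_sd = 0` and all CVs zero it reproduces measured free phenytoin
to machine precision, which is what makes parameter recovery a meaningful
test (and `icu_binding_shift` exists to create deliberate inpatient
misspecification when wanted). What the generator does **not** emulate:
joint covariate structure (marginals are matched, independence assumed —
e.g. pediatric ages are not tied to pediatric wards), uremia or
displacement-drug effects on binding, assay changes over calendar time, and
any dose–concentration feedback. Passing tests therefore show the pipeline
is correct and the correction recovers a Sheiner–Tozer-consistent world;
they do not show the correction is well specified for real patients — the
evaluation on real data is exactly what the pipeline exists to perform.

## Problem sizes and determinism

Everything is reproducible from `(config, seed)`: two runs write
byte-identical event files and reports. The test suite works at the default
cohort size (756 patients / 1753 observations), where the full pipeline runs
in about a second; the Monte-Carlo stratum-mean check uses 2000 patients;
oracle property tests use 500 enumerated Fisher tables and 100 random
regression fixtures.

## Limitations

The package evaluates one correction against one reference; it does not fit
improved binding models, handle HL7/FHIR ingestion, or model
pharmacokinetics. Percentages are exact fractions until the reporting layer;
serialized tables always allow every printed percentage to be recomputed.
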