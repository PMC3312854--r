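# phtadjust

Tools for evaluating the **albumin-adjusted ("Sheiner–Tozer") free
phenytoin** estimate against directly measured free phenytoin in a
therapeutic-drug-monitoring cohort.

Phenytoin is monitored through plasma concentrations because its
pharmacokinetics are nonlinear and its toxic and therapeutic windows are
close. The routinely measured *total* concentration (therapeutic range
10–20 mg/L) counts both protein-bound and free drug, but only the free
portion (range 1–2 mg/L, ~10% of total under normal binding) is active. In
hypoalbuminemia the free fraction rises and total phenytoin becomes
misleading. The albumin correction estimates the free level from the total
and the plasma albumin (g/dL):

```
C_adj_free = [ C_total / (0.2 × Alb + 0.1) ] / 10
```

`phtadjust` is aimed at laboratorians and clinical-informatics researchers
who want to quantify how well this correction — or plain total/10 — stands in
for a measured free level. It provides:

* the correction, its implied free fraction, and closed-interval L/T/H
  therapeutic-range classification (`sheiner_tozer_adjust()`, `classify()`);
* lab-record linkage: same-draw total/free pairing, a 7-day albumin lookback
  with a full linkage log, first-per-patient deduplication, and
  consecutive-pair extraction (`link_observations()` and friends);
* 3×3 therapeutic-category concordance tables with
  under/concordant/over rates, Fisher/chi-squared/McNemar method
  comparisons, and consecutive-measurement stability (`build_table()`,
  `compare_methods()`, `stability_rate()`);
* continuous agreement statistics: Pearson r, OLS with 95% CIs and
  identity-line tests, Bland–Altman limits of agreement,
  difference-vs-covariate regressions, ANOVA and t-tests (`ols_fit()`,
  `bland_altman()`, …);
* a synthetic cohort generator emulating a large hospital monitoring
  population (756 patients, 1753 observations, inpatient-weighted
  hypoalbuminemia, 0–7-day albumin lags, repeat draws with dosing drift)
  with full ground truth for parameter recovery (`generate_cohort()`);
* an orchestrated pipeline and serialized report (`run_pht_analysis()`,
  `write_report()`).

## Worked example

```r
library(phtadjust)

# a single hypoalbuminemic patient: "therapeutic" total, toxic free estimate
sheiner_tozer_adjust(total = 15, albumin = 2.0)
#> [1] 3
classify(3, range_free())
#> [1] H
#> Levels: L < T < H

# full synthetic-cohort evaluation
gen <- generate_cohort(default_config())
report <- run_pht_analysis(gen$events, gen$covariates)
print(report)
#> Phenytoin monitoring analysis
#>   1753 observations linked from 756 patients (0 dropped)
#>   [first] concordance vs measured free: total 52.5%, adjusted 73.5% (Fisher p = 2.66e-17)
#>   [all] concordance vs measured free: total 56.6%, adjusted 74.3% (Fisher p = 2.05e-28)
#>   [first] free ~ total/10: r = 0.75, fit 0.123 + 1.419 x
#>   [first] free ~ adjusted: r = 0.82, fit 0.133 + 0.981 x
#>   stability over 997 consecutive pairs: total 54.3%, adjusted 54.1%
```

Reading: classifying patients by total phenytoin agrees with the measured
free category barely half the time, while the albumin-adjusted estimate
agrees about three-quarters of the time (Fisher p ≪ 0.001), and its
regression against measured free runs close to the identity line
(slope 0.981). Category assignments are only ~54% stable between a patient's
consecutive draws, reflecting dose changes between measurements.

The numbered scripts under `analysis/` run the same workflow as a
step-by-step narrative (simulate → link → concordance → agreement → report),
writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_link.R
Rscript analysis/03_concordance.R
Rscript analysis/04_agreement.R
Rscript analysis/05_report.R
```

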