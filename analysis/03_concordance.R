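#!/usr/bin/env Rscript
# Therapeutic-category concordance: 3x3 tables of total phenytoin and of
# the albumin-adjusted estimate against measured free phenytoin, the
# Fisher/chi-squared method comparison, and the stability of category
# cells across consecutive within-patient draws.
suppressPackageStartupMessages(library(phtadjust))

obs <- read_cohort("results/cohort_linked.csv")
obs <- derive_quantities(obs)
first <- first_per_patient(obs)

for (variant in list(list(d = first, tag = "first"),
                     list(d = obs, tag = "all"))) {
  d <- variant$d
  tab_total <- build_table(d$cat_total, d$cat_free, "total", "free")
  tab_adj <- build_table(d$cat_adj, d$cat_free, "adjusted", "free")
  st <- summarize_table(tab_total)
  sa <- summarize_table(tab_adj)
  cmp <- compare_methods(d$cat_adj, d$cat_total, d$cat_free,
                         c("adjusted", "total"))
  cat(sprintf(
    "[%s, N=%d] total vs free: %.1f%% concordant (%.1f%% under, %.1f%% over)\n",
    variant$tag, st$n, st$concordant_pct, st$under_pct, st$over_pct))
  cat(sprintf(
    "[%s, N=%d] adjusted vs free: %.1f%% concordant (%.1f%% under, %.1f%% over)\n",
    variant$tag, sa$n, sa$concordant_pct, sa$under_pct, sa$over_pct))
  cat(sprintf("[%s] adjusted vs total: Fisher p = %.3g, chi-squared p = %.3g, McNemar p = %.3g\n",
              variant$tag, cmp$fisher_p, cmp$chi_squared$p, cmp$mcnemar_p))
  for (tb in list(list(tab_total, "total"), list(tab_adj, "adj"))) {
    df <- as.data.frame(as.table(unclass(tb[[1]])))
    names(df) <- c("comparator", "reference", "count")
    readr::write_csv(df, sprintf("results/table_%s_vs_free_%s.csv",
                                 tb[[2]], variant$tag))
  }
}

pairs <- consecutive_pairs(obs)
free_rng <- range_free(); total_rng <- range_total()
stab_total <- stability_rate(
  classify(pairs$prev_pht_total, total_rng),
  classify(pairs$prev_pht_free, free_rng),
  classify(pairs$next_pht_total, total_rng),
  classify(pairs$next_pht_free, free_rng))
stab_adj <- stability_rate(
  classify(sheiner_tozer_adjust(pairs$prev_pht_total, pairs$prev_albumin), free_rng),
  classify(pairs$prev_pht_free, free_rng),
  classify(sheiner_tozer_adjust(pairs$next_pht_total, pairs$next_albumin), free_rng),
  classify(pairs$next_pht_free, free_rng))
cat(sprintf("Stability over %d consecutive pairs: total %.1f%% (%d/%d), adjusted %.1f%% (%d/%d)\n",
            nrow(pairs), stab_total$pct, stab_total$agree, stab_total$total,
            stab_adj$pct, stab_adj$agree, stab_adj$total))
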