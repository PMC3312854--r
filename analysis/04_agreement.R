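#!/usr/bin/env Rscript
# Continuous-scale agreement with measured free phenytoin: Pearson
# correlations, least-squares fits with identity-line tests,
# Bland-Altman bias, difference-vs-albumin/age regressions, and the
# sex/lag/location/year group comparisons.
suppressPackageStartupMessages(library(phtadjust))

obs <- derive_quantities(read_cohort("results/cohort_linked.csv"))
first <- first_per_patient(obs)

describe_fit <- function(x, y, label) {
  fit <- ols_fit(x, y)
  idt <- slope_test(fit, 1)
  cat(sprintf(
    "%s: r = %.3f, y = %.3f + %.3f x, slope CI (%.3f, %.3f), identity p = %.3g\n",
    label, pearson_r(x, y), fit$intercept, fit$slope,
    fit$slope_ci95[1], fit$slope_ci95[2], idt$p))
  invisible(fit)
}
describe_fit(first$pht_total_scaled, first$pht_free,
             "[first] free ~ total/10 ")
describe_fit(first$pht_adj_free, first$pht_free,
             "[first] free ~ adjusted ")
describe_fit(obs$pht_total_scaled, obs$pht_free,
             "[all]   free ~ total/10 ")
describe_fit(obs$pht_adj_free, obs$pht_free,
             "[all]   free ~ adjusted ")

ba <- bland_altman(first$pht_total_scaled, first$pht_free, "absolute")
cat(sprintf("Bland-Altman total/10 - free: bias %.3f mg/L, LoA (%.3f, %.3f)\n",
            ba$bias, ba$loa_low, ba$loa_high))

d_total <- first$pht_total_scaled - first$pht_free
d_adj <- first$pht_free - first$pht_adj_free
for (reg in list(
  list(d_total, first$albumin, "(total/10 - free) ~ albumin"),
  list(d_adj, first$albumin, "(free - adjusted) ~ albumin"),
  list(d_total, first$age, "(total/10 - free) ~ age"),
  list(d_adj, first$age, "(free - adjusted) ~ age"))) {
  fit <- diff_vs_covariate(reg[[1]], reg[[2]])
  zt <- slope_test(fit, 0)
  cat(sprintf("%s: %.3f + %.3f x, slope CI (%.3f, %.3f), p(slope=0) = %.3g\n",
              reg[[3]], fit$intercept, fit$slope,
              fit$slope_ci95[1], fit$slope_ci95[2], zt$p))
}

d_adj_all <- obs$pht_free - obs$pht_adj_free
tt <- unpaired_t(d_adj_all[obs$sex == "male"], d_adj_all[obs$sex == "female"])
cat(sprintf("male vs female (free - adjusted): t = %.2f, p = %.3g\n",
            tt$t, tt$p))
for (g in list(list(obs$lag_days, "lag days"),
               list(obs$location, "location"),
               list(obs$year, "year"))) {
  an <- group_anova(d_adj_all, g[[1]])
  cat(sprintf("ANOVA of (free - adjusted) across %s: F(%d, %d) = %.2f, p = %.3g\n",
              g[[2]], an$df_between, an$df_within, an$F, an$p))
}
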