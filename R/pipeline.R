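#' Derive adjusted concentrations and therapeutic categories
#'
#' Adds to a linked cohort the albumin-adjusted free phenytoin
#' (`pht_adj_free`), total phenytoin on the free scale
#' (`pht_total_scaled`), and the three therapeutic categories:
#' `cat_free` (measured free vs 1-2 mg/L), `cat_adj` (adjusted free vs
#' 1-2 mg/L) and `cat_total` (total vs 10-20 mg/L).
#'
#' @param obs Linked-observation tibble from [link_observations()].
#' @param coeffs Adjustment coefficients.
#' @return `obs` with the derived columns appended.
#' @export
derive_quantities <- function(obs, coeffs = adjustment_coefficients()) {
  free_rng <- range_free()
  total_rng <- range_total()
  obs$pht_adj_free <- sheiner_tozer_adjust(obs$pht_total, obs$albumin,
                                           coeffs)
  obs$pht_total_scaled <- scale_total(obs$pht_total)
  obs$cat_free <- classify(obs$pht_free, free_rng)
  obs$cat_adj <- classify(obs$pht_adj_free, free_rng)
  obs$cat_total <- classify(obs$pht_total, total_rng)
  obs
}

summarize_cohort <- function(obs_first) {
  tibble::tibble(
    n_patients = nrow(obs_first),
    n_male = if ("sex" %in% names(obs_first))
      sum(obs_first$sex == "male") else NA_integer_,
    mean_age = if ("age" %in% names(obs_first))
      mean(obs_first$age) else NA_real_,
    mean_albumin = mean(obs_first$albumin),
    median_total = stats::median(obs_first$pht_total),
    median_free = stats::median(obs_first$pht_free)
  )
}

concordance_block <- function(obs, variant) {
  tab_total <- build_table(obs$cat_total, obs$cat_free,
                           comparator_name = "total phenytoin",
                           reference_name = "measured free")
  tab_adj <- build_table(obs$cat_adj, obs$cat_free,
                         comparator_name = "adjusted free",
                         reference_name = "measured free")
  list(
    variant = variant,
    table_total_vs_free = tab_total,
    table_adj_vs_free = tab_adj,
    summary_total_vs_free = summarize_table(tab_total),
    summary_adj_vs_free = summarize_table(tab_adj),
    method_comparison = compare_methods(
      obs$cat_adj, obs$cat_total, obs$cat_free,
      names_ab = c("adjusted free", "total"))
  )
}

fit_block <- function(obs, variant) {
  list(
    variant = variant,
    n = nrow(obs),
    pearson_total = pearson_r(obs$pht_total_scaled, obs$pht_free),
    pearson_adj = pearson_r(obs$pht_adj_free, obs$pht_free),
    fit_free_vs_total_scaled = ols_fit(obs$pht_total_scaled, obs$pht_free),
    fit_free_vs_adj = ols_fit(obs$pht_adj_free, obs$pht_free),
    identity_test_total = slope_test(
      ols_fit(obs$pht_total_scaled, obs$pht_free), 1),
    identity_test_adj = slope_test(ols_fit(obs$pht_adj_free, obs$pht_free),
                                   1),
    bland_altman_abs = bland_altman(obs$pht_total_scaled, obs$pht_free,
                                    "absolute"),
    bland_altman_pct = tryCatch(
      bland_altman(obs$pht_total_scaled, obs$pht_free, "percent"),
      error = function(e) NULL)
  )
}

difference_block <- function(obs) {
  d_total <- obs$pht_total_scaled - obs$pht_free
  d_adj <- obs$pht_free - obs$pht_adj_free
  out <- list(
    diff_total_vs_albumin = diff_vs_covariate(d_total, obs$albumin),
    diff_adj_vs_albumin = diff_vs_covariate(d_adj, obs$albumin),
    mean_free_minus_total_scaled = mean(-d_total)
  )
  if ("age" %in% names(obs)) {
    out$diff_total_vs_age <- diff_vs_covariate(d_total, obs$age)
    out$diff_adj_vs_age <- diff_vs_covariate(d_adj, obs$age)
  }
  out
}

group_block <- function(obs) {
  d_adj <- obs$pht_free - obs$pht_adj_free
  out <- list()
  if ("sex" %in% names(obs) && length(unique(obs$sex)) == 2L) {
    out$sex_t_test <- unpaired_t(d_adj[obs$sex == "male"],
                                 d_adj[obs$sex == "female"])
  }
  if (length(unique(obs$lag_days)) > 1L) {
    out$lag_anova <- group_anova(d_adj, obs$lag_days)
  }
  if ("location" %in% names(obs) && length(unique(obs$location)) > 1L) {
    out$location_anova <- group_anova(d_adj, obs$location)
  }
  if (length(unique(obs$year)) > 1L) {
    out$year_anova <- group_anova(d_adj, obs$year)
  }
  out
}

stability_block <- function(obs) {
  pairs <- consecutive_pairs(obs)
  if (nrow(pairs) == 0L) return(NULL)
  free_rng <- range_free()
  total_rng <- range_total()
  cat_of <- function(total, free) {
    list(total = classify(total, total_rng),
         adj_ref = classify(free, free_rng))
  }
  prev_free <- classify(pairs$prev_pht_free, free_rng)
  next_free <- classify(pairs$next_pht_free, free_rng)
  prev_total <- classify(pairs$prev_pht_total, total_rng)
  next_total <- classify(pairs$next_pht_total, total_rng)
  prev_adj <- classify(
    sheiner_tozer_adjust(pairs$prev_pht_total, pairs$prev_albumin),
    free_rng)
  next_adj <- classify(
    sheiner_tozer_adjust(pairs$next_pht_total, pairs$next_albumin),
    free_rng)
  list(
    n_pairs = nrow(pairs),
    total_vs_free = stability_rate(prev_total, prev_free,
                                   next_total, next_free),
    adj_vs_free = stability_rate(prev_adj, prev_free,
                                 next_adj, next_free)
  )
}

#' Run the full monitoring-cohort analysis
#'
#' Orchestrates linkage, adjustment, classification, concordance,
#' agreement statistics, subgroup tests and the stability analysis for
#' a cohort of lab events, reproducing each analysis in two variants:
#' the chronologically first observation per patient (between-patient)
#' and all observations including repeats. The result is a structured
#' report; [write_report()] serializes it.
#'
#' @param events Lab-event tibble (from [read_lab_events()] or
#'   [generate_cohort()]).
#' @param covariates Per-patient covariate tibble, or `NULL`.
#' @param window_days Albumin lookback window, days.
#' @param coeffs Adjustment coefficients.
#' @return A list of class `pht_report` with elements `cohort`,
#'   `linkage_log`, `concordance` (`first`, `all`), `fits` (`first`,
#'   `all`), `differences`, `groups`, `stability`, and the derived
#'   observation tables `obs_all` / `obs_first`.
#' @export
run_pht_analysis <- function(events, covariates = NULL, window_days = 7,
                             coeffs = adjustment_coefficients()) {
  obs <- link_observations(events, covariates, window_days)
  if (nrow(obs) == 0L) {
    stop("linkage produced zero observations", call. = FALSE)
  }
  log <- linkage_log(obs)
  obs <- derive_quantities(obs, coeffs)
  obs_first <- first_per_patient(obs)

  report <- list(
    cohort = summarize_cohort(obs_first),
    linkage_log = log,
    concordance = list(first = concordance_block(obs_first, "first"),
                       all = concordance_block(obs, "all")),
    fits = list(first = fit_block(obs_first, "first"),
                all = fit_block(obs, "all")),
    differences = difference_block(obs_first),
    groups = group_block(obs),
    stability = stability_block(obs),
    obs_all = obs,
    obs_first = obs_first
  )
  class(report) <- "pht_report"
  report
}

fmt_pct <- function(x) sprintf("%.1f%%", x)

#' @export
print.pht_report <- function(x, ...) {
  cat("Phenytoin monitoring analysis\n")
  cat(sprintf("  %d observations linked from %d patients (%d dropped)\n",
              x$linkage_log$n_linked, x$cohort$n_patients,
              x$linkage_log$n_dropped_no_albumin))
  for (v in c("first", "all")) {
    cb <- x$concordance[[v]]
    cat(sprintf(
      "  [%s] concordance vs measured free: total %s, adjusted %s (Fisher p = %.3g)\n",
      v, fmt_pct(cb$summary_total_vs_free$concordant_pct),
      fmt_pct(cb$summary_adj_vs_free$concordant_pct),
      cb$method_comparison$fisher_p))
  }
  fb <- x$fits$first
  cat(sprintf(
    "  [first] free ~ total/10: r = %.2f, fit %.3f + %.3f x\n",
    fb$pearson_total, fb$fit_free_vs_total_scaled$intercept,
    fb$fit_free_vs_total_scaled$slope))
  cat(sprintf(
    "  [first] free ~ adjusted: r = %.2f, fit %.3f + %.3f x\n",
    fb$pearson_adj, fb$fit_free_vs_adj$intercept,
    fb$fit_free_vs_adj$slope))
  if (!is.null(x$stability)) {
    cat(sprintf(
      "  stability over %d consecutive pairs: total %s, adjusted %s\n",
      x$stability$n_pairs, fmt_pct(x$stability$total_vs_free$pct),
      fmt_pct(x$stability$adj_vs_free$pct)))
  }
  invisible(x)
}

ct3_as_df <- function(tab) {
  df <- as.data.frame(as.table(unclass(tab)))
  names(df) <- c("comparator", "reference", "count")
  df
}

#' Serialize an analysis report
#'
#' Writes the report's tables as CSV files plus a human-readable
#' `report.txt` (including the linkage log) into a directory. Every
#' percentage in the text report is recomputable from the serialized
#' tables it accompanies. All p-values are unadjusted: no
#' multiple-testing correction is applied anywhere in the analysis.
#'
#' @param report A `pht_report` from [run_pht_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (v in c("first", "all")) {
    cb <- report$concordance[[v]]
    readr::write_csv(ct3_as_df(cb$table_total_vs_free),
                     file.path(dir, paste0("table_total_vs_free_", v, ".csv")),
                     progress = FALSE)
    readr::write_csv(ct3_as_df(cb$table_adj_vs_free),
                     file.path(dir, paste0("table_adj_vs_free_", v, ".csv")),
                     progress = FALSE)
  }
  write_cohort(report$obs_first, file.path(dir, "cohort_first.csv"))

  txt <- file.path(dir, "report.txt")
  con <- file(txt, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Phenytoin monitoring analysis report")
  w("Linkage: %d pairs, %d linked, %d dropped without eligible albumin, %d duplicates resolved",
    report$linkage_log$n_phenytoin_pairs, report$linkage_log$n_linked,
    report$linkage_log$n_dropped_no_albumin,
    report$linkage_log$n_duplicate_results_dropped)
  for (v in c("first", "all")) {
    cb <- report$concordance[[v]]
    st <- cb$summary_total_vs_free
    sa <- cb$summary_adj_vs_free
    w("[%s] total vs free: concordant %.1f%%, under %.1f%%, over %.1f%% (N = %d)",
      v, st$concordant_pct, st$under_pct, st$over_pct, st$n)
    w("[%s] adjusted vs free: concordant %.1f%%, under %.1f%%, over %.1f%% (N = %d)",
      v, sa$concordant_pct, sa$under_pct, sa$over_pct, sa$n)
    w("[%s] method comparison Fisher p = %.4g (chi-squared p = %.4g, McNemar p = %.4g); p-values unadjusted",
      v, cb$method_comparison$fisher_p, cb$method_comparison$chi_squared$p,
      cb$method_comparison$mcnemar_p)
  }
  fb <- report$fits$first
  w("[first] free ~ total/10: r = %.4f, fit %.4f + %.4f x, slope CI (%.4f, %.4f)",
    fb$pearson_total, fb$fit_free_vs_total_scaled$intercept,
    fb$fit_free_vs_total_scaled$slope,
    fb$fit_free_vs_total_scaled$slope_ci95[1],
    fb$fit_free_vs_total_scaled$slope_ci95[2])
  w("[first] free ~ adjusted: r = %.4f, fit %.4f + %.4f x, slope CI (%.4f, %.4f)",
    fb$pearson_adj, fb$fit_free_vs_adj$intercept, fb$fit_free_vs_adj$slope,
    fb$fit_free_vs_adj$slope_ci95[1], fb$fit_free_vs_adj$slope_ci95[2])
  d <- report$differences
  w("[first] (total/10 - free) ~ albumin: %.4f + %.4f x, slope CI (%.4f, %.4f)",
    d$diff_total_vs_albumin$intercept, d$diff_total_vs_albumin$slope,
    d$diff_total_vs_albumin$slope_ci95[1],
    d$diff_total_vs_albumin$slope_ci95[2])
  if (!is.null(report$stability)) {
    w("stability over %d pairs: total vs free %.1f%% (%d/%d), adjusted vs free %.1f%% (%d/%d)",
      report$stability$n_pairs,
      report$stability$total_vs_free$pct, report$stability$total_vs_free$agree,
      report$stability$total_vs_free$total,
      report$stability$adj_vs_free$pct, report$stability$adj_vs_free$agree,
      report$stability$adj_vs_free$total)
  }
  invisible(dir)
}
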