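test_that("default configuration mirrors the reference cohort marginals", {
  cfg <- default_config()
  expect_equal(cfg$n_patients, 756)
  # expected observations = patients * (1 + repeat rate) = 1753
  expect_equal(cfg$n_patients * (1 + cfg$repeat_measure_rate), 1753)
  expect_equal(cfg$sex_ratio, 422 / 756)
  expect_equal(cfg$seizure24h_rate, 263 / 756)
  expect_equal(cfg$comed_weights[1], 371 / 756)
  expect_equal(cfg$lag_days_weights,
               c(559, 290, 215, 190, 152, 103, 112, 132) / 1753)
  expect_equal(sum(cfg$location_weights), 1)
  expect_equal(sum(cfg$age_bands$weight), 1)
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(cohort_config(n_patients = 0), "positive integer")
  expect_error(cohort_config(sex_ratio = 1.2), "0, 1")
  expect_error(cohort_config(comed_weights = c(0.5, 0.5, 0.1, 0)), "sum to 1")
  expect_error(cohort_config(lag_days_weights = rep(1 / 4, 4)), "8 entries")
  expect_error(cohort_config(binding_sd = -0.1), "non-negative")
  expect_error(cohort_config(albumin_mean_by_location = c(
    adult_inpatient = 3.1, peds_inpatient = 3.4, icu = 0.5, emergency = 3.8,
    primary_care = 4.2, other_outpatient = 4.0)), "truncation bounds")
  expect_error(generate_cohort(list(n_patients = 5)), "cohort_config")
})

test_that("configurations round-trip through JSON", {
  cfg <- cohort_config(n_patients = 42, binding_sd = 0.3, seed = 9)
  path <- tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)
})

test_that("generation is deterministic and conserves event structure", {
  cfg <- cohort_config(n_patients = 80, seed = 14)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)
  # byte-identical files from the same seed
  p1 <- tempfile(); p2 <- tempfile()
  write_lab_events(g1$events, p1)
  write_lab_events(g2$events, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the draw
  expect_false(identical(
    generate_cohort(cohort_config(n_patients = 80, seed = 15)), g1))

  # every observation contributes one albumin, one total, one free event
  counts <- table(g1$events$analyte)
  expect_equal(unname(counts["albumin"]), unname(counts["pht_total"]))
  expect_equal(unname(counts["pht_free"]), unname(counts["pht_total"]))
  expect_equal(nrow(g1$truth), unname(counts["pht_total"]))

  # linkage recovers every generated pair: exactly one eligible albumin each
  obs <- link_observations(g1$events, g1$covariates)
  log <- linkage_log(obs)
  expect_equal(log$n_linked, nrow(g1$truth))
  expect_equal(log$n_dropped_no_albumin, 0L)
  expect_equal(nrow(first_per_patient(obs)), cfg$n_patients)
})

test_that("ground truth obeys the generative free-fraction model", {
  cfg <- cohort_config(n_patients = 120, seed = 16)
  g <- generate_cohort(cfg)
  expect_equal(g$truth$free_true, g$truth$fu * g$truth$total_true)
  expect_true(all(g$truth$fu > 0 & g$truth$fu <= 1))
  expect_true(all(g$truth$albumin_true > 1 & g$truth$albumin_true < 6))
  expect_equal(
    g$truth$fu,
    pmin(1, 0.1 * exp(g$truth$eta) / (0.2 * g$truth$albumin_true + 0.1)))
})

test_that("stratum albumin means are recovered at Monte-Carlo tolerance", {
  cfg <- cohort_config(
    n_patients = 2000,
    location_weights = c(adult_inpatient = 0, peds_inpatient = 0, icu = 1,
                         emergency = 0, primary_care = 0,
                         other_outpatient = 0),
    albumin_mean_by_location = c(adult_inpatient = 3.1, peds_inpatient = 3.4,
                                 icu = 2.5, emergency = 3.8,
                                 primary_care = 4.2, other_outpatient = 4.0),
    repeat_measure_rate = 0, seed = 17)
  g <- generate_cohort(cfg)
  expect_true(all(g$covariates$location == "icu"))
  se <- cfg$albumin_sd / sqrt(2000)
  # truncation to (1, 6) barely moves the mean at sd 0.55
  expect_lt(abs(mean(g$truth$albumin_true) - 2.5), 3 * se + 0.01)
})

test_that("noise-free cohorts make the adjustment exact and defaults lean under", {
  g <- generate_cohort(noise_free_config(seed = 18, n = 150))
  obs <- derive_quantities(link_observations(g$events, g$covariates))
  expect_equal(obs$pht_adj_free, obs$pht_free, tolerance = 1e-12)
  expect_true(all(obs$cat_adj == obs$cat_free))

  # with default noise, free generally exceeds total/10 (hypoalbuminemia)
  gd <- generate_cohort(cohort_config(seed = 19))
  od <- derive_quantities(link_observations(gd$events, gd$covariates))
  expect_gt(mean(od$pht_free - od$pht_total_scaled), 0)
})

test_that("truth report scores comparators against generator ground truth", {
  g <- generate_cohort(noise_free_config(seed = 27, n = 200))
  obs <- link_observations(g$events, g$covariates)
  tr <- truth_report(g$truth, obs)
  expect_equal(tr$concordance_adj_vs_truth_pct, 100)
  expect_equal(tr$slope_free_vs_adj, 1, tolerance = 1e-9)

  # hypoalbuminemic noise-free cohort: total/10 under-calls the truth
  cfg <- cohort_config(
    n_patients = 200, binding_sd = 0, assay_cv_total = 0, assay_cv_free = 0,
    assay_cv_albumin = 0,
    location_weights = c(adult_inpatient = 0, peds_inpatient = 0, icu = 1,
                         emergency = 0, primary_care = 0,
                         other_outpatient = 0),
    albumin_mean_by_location = c(adult_inpatient = 3.1, peds_inpatient = 3.4,
                                 icu = 2.5, emergency = 3.8,
                                 primary_care = 4.2, other_outpatient = 4.0),
    seed = 28)
  g2 <- generate_cohort(cfg)
  obs2 <- link_observations(g2$events, g2$covariates)
  tr2 <- truth_report(g2$truth, obs2)
  expect_lt(tr2$concordance_scaled_vs_truth_pct, 100)
  expect_equal(tr2$concordance_adj_vs_truth_pct, 100)

  expect_error(truth_report(g$truth[-1, ], obs), "do not match")
})
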