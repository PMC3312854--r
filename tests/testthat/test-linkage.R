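test_that("lab-event files parse, convert albumin units, and reject bad rows", {
  p <- write_event_csv(c(
    event_row("A", "2004-01-01T09:30:00", "pht_total", 11, "mg/L"),
    event_row("A", "2004-01-01T09:30:00", "pht_free", 1.2, "mg/L"),
    event_row("A", "2003-12-30T07:00:00", "albumin", 35, "g/L")
  ))
  ev <- read_lab_events(p)
  expect_equal(nrow(ev), 3L)
  # g/L albumin stored as g/dL
  expect_equal(ev$value[ev$analyte == "albumin"], 3.5)
  expect_equal(ev$unit[ev$analyte == "albumin"], "g/dL")
  expect_s3_class(ev$timestamp, "POSIXct")

  bad <- write_event_csv(c(
    event_row("A", "2004-01-01T09:30:00", "phenytoin??", 11, "mg/L"),
    event_row("A", "not-a-time", "pht_free", 1.2, "mg/L"),
    event_row("A", "2004-01-01T09:30:00", "pht_total", "eleven", "mg/L"),
    event_row("A", "2004-01-01T09:30:00", "albumin", 3.5, "furlongs")
  ))
  expect_error(read_lab_events(bad), "row 1.*unknown analyte")
  expect_error(read_lab_events(bad), "row 2.*timestamp")
  expect_error(read_lab_events(bad), "row 3.*non-negative")
  expect_error(read_lab_events(bad), "row 4.*unit tag")

  nohdr <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,when,analyte,value,unit", "A,2004-01-01,albumin,3.5,g/dL"), nohdr)
  expect_error(read_lab_events(nohdr), "missing required column.*timestamp")
  expect_error(read_lab_events(tempfile()), "does not exist")
})

test_that("linkage pairs same-draw phenytoin and attaches the most recent in-window albumin", {
  obs <- link_observations(read_lab_events(linkage_fixture_path()))
  expect_equal(nrow(obs), 3L)
  expect_setequal(obs$patient_id, c("P1", "P2", "P3"))
  expect_equal(sort(obs$lag_days), c(0, 3, 7))
  log <- linkage_log(obs)
  expect_equal(log$n_phenytoin_pairs, 4L)           # P5 never forms a pair
  expect_equal(log$n_dropped_no_albumin, 1L)        # P4's albumin is 8 days old
  expect_equal(log$n_unpaired_phenytoin_events, 2L) # P5's mismatched events
  expect_equal(log$n_linked + log$n_dropped_no_albumin, log$n_phenytoin_pairs)

  # most-recent-within-window rule:
  # draw at day 10 with albumins at days 4 and 7 -> day-7 albumin, lag 3
  p <- write_event_csv(c(
    event_row("Q", "2004-01-04T08:00:00", "albumin", 4.0, "g/dL"),
    event_row("Q", "2004-01-07T08:00:00", "albumin", 2.0, "g/dL"),
    event_row("Q", "2004-01-10T08:00:00", "pht_total", 12, "mg/L"),
    event_row("Q", "2004-01-10T08:00:00", "pht_free", 1.4, "mg/L")
  ))
  obs2 <- link_observations(read_lab_events(p))
  expect_equal(obs2$albumin, 2.0)
  expect_equal(obs2$lag_days, 3)

  # an albumin measured after the draw is never selected
  p3 <- write_event_csv(c(
    event_row("R", "2004-01-11T08:00:00", "albumin", 4.0, "g/dL"),
    event_row("R", "2004-01-10T08:00:00", "pht_total", 12, "mg/L"),
    event_row("R", "2004-01-10T08:00:00", "pht_free", 1.4, "mg/L")
  ))
  expect_equal(nrow(link_observations(read_lab_events(p3))), 0L)
})

test_that("degenerate inputs resolve deterministically and are logged", {
  # duplicate same-draw same-analyte result: first in input order wins
  p <- write_event_csv(c(
    event_row("S", "2004-01-10T08:00:00", "pht_total", 12, "mg/L"),
    event_row("S", "2004-01-10T08:00:00", "pht_total", 99, "mg/L"),
    event_row("S", "2004-01-10T08:00:00", "pht_free", 1.4, "mg/L"),
    event_row("S", "2004-01-10T08:00:00", "albumin", 3.0, "g/dL")
  ))
  expect_warning(obs <- link_observations(read_lab_events(p)), "duplicate")
  expect_equal(obs$pht_total, 12)
  expect_equal(linkage_log(obs)$n_duplicate_results_dropped, 1L)

  # albumin tie at identical timestamps: last in input order wins
  p2 <- write_event_csv(c(
    event_row("U", "2004-01-08T08:00:00", "albumin", 3.0, "g/dL"),
    event_row("U", "2004-01-08T08:00:01", "albumin", 2.0, "g/dL"),
    event_row("U", "2004-01-08T08:00:01", "albumin", 2.5, "g/dL"),
    event_row("U", "2004-01-10T08:00:00", "pht_total", 12, "mg/L"),
    event_row("U", "2004-01-10T08:00:00", "pht_free", 1.4, "mg/L")
  ))
  expect_warning(obs2 <- link_observations(read_lab_events(p2)), "tie")
  expect_equal(obs2$albumin, 2.5)
  expect_equal(linkage_log(obs2)$n_albumin_ties, 1L)
})

test_that("first_per_patient keeps the earliest draw and is idempotent", {
  obs <- tibble::tibble(
    patient_id = c("A", "A", "A", "B"),
    draw_time = as.POSIXct(c("2004-01-09 08:00:00", "2004-01-01 08:00:00",
                             "2004-01-05 08:00:00", "2004-02-01 08:00:00"),
                           tz = "UTC"),
    pht_total = c(1, 2, 3, 4), pht_free = c(1, 2, 3, 4) / 10,
    albumin = rep(4, 4), lag_days = rep(0, 4))
  f <- first_per_patient(obs)
  expect_equal(nrow(f), 2L)
  expect_equal(f$pht_total[f$patient_id == "A"], 2)
  expect_identical(first_per_patient(f), f)
  expect_equal(nrow(first_per_patient(obs[0, ])), 0L)
})

test_that("consecutive pairs number observations minus patients", {
  obs <- tibble::tibble(
    patient_id = c("A", "A", "A", "B", "C", "C"),
    draw_time = as.POSIXct("2004-01-01", tz = "UTC") + c(1, 30, 60, 1, 1, 9) * 86400,
    pht_total = 1:6, pht_free = (1:6) / 10, albumin = rep(3, 6),
    lag_days = rep(0, 6))
  pairs <- consecutive_pairs(obs)
  expect_equal(nrow(pairs), 3L)  # (3-1) + 0 + (2-1)
  expect_equal(pairs$prev_pht_total[pairs$patient_id == "A"], c(1, 2))
  expect_equal(pairs$next_pht_total[pairs$patient_id == "A"], c(2, 3))
  expect_equal(nrow(consecutive_pairs(obs[c(4, 5), ])), 0L)
})

test_that("cohort files round-trip at full precision", {
  set.seed(4)
  obs <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    draw_time = as.POSIXct("2004-01-01 08:00:00", tz = "UTC") + (1:10) * 86400,
    pht_total = runif(10, 2, 35), pht_free = runif(10, 0.2, 4),
    albumin = runif(10, 1.2, 5.8), lag_days = sample(0:7, 10, TRUE),
    year = rep(2004L, 10), age = runif(10, 1, 90),
    sex = sample(c("male", "female"), 10, TRUE),
    location = sample(c("icu", "adult_inpatient"), 10, TRUE),
    seizure_24h = sample(c(TRUE, FALSE), 10, TRUE),
    n_additional_aeds = sample(0:3, 10, TRUE))
  path <- tempfile(fileext = ".csv")
  write_cohort(obs, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(obs))

  # empty cohort -> header-only file that reads back empty
  write_cohort(obs[0, ], path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 0L)

  # lab events round-trip too
  g <- generate_cohort(cohort_config(n_patients = 5, seed = 3))
  ep <- tempfile(fileext = ".csv")
  write_lab_events(g$events, ep)
  expect_equal(as.data.frame(read_lab_events(ep)), as.data.frame(g$events))
})
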