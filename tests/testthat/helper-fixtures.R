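# Small in-code fixtures shared across test files.

event_row <- function(patient, ts, analyte, value, unit) {
  sprintf("%s,%s,%s,%s,%s", patient, ts, analyte, value, unit)
}

write_event_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("patient_id,timestamp,analyte,value,unit", rows), path)
  path
}

# Hand-written 12-event linkage fixture: three valid draws with albumin
# lags 0, 3 and 7 days, one draw whose only albumin is 8 days old, and a
# total/free pair one day apart (no same-draw pair).
linkage_fixture_path <- function() {
  rows <- c(
    # P1: lag 0 (same-timestamp albumin)
    event_row("P1", "2005-03-10T08:00:00", "albumin", 3.0, "g/dL"),
    event_row("P1", "2005-03-10T08:00:00", "pht_total", 12, "mg/L"),
    event_row("P1", "2005-03-10T08:00:00", "pht_free", 1.4, "mg/L"),
    # P2: lag 3
    event_row("P2", "2005-03-07T08:00:00", "albumin", 2.5, "g/dL"),
    event_row("P2", "2005-03-10T08:00:00", "pht_total", 18, "mg/L"),
    event_row("P2", "2005-03-10T08:00:00", "pht_free", 2.9, "mg/L"),
    # P3: lag 7 (exactly at the window edge)
    event_row("P3", "2005-03-03T08:00:00", "albumin", 4.5, "g/dL"),
    event_row("P3", "2005-03-10T08:00:00", "pht_total", 10, "mg/L"),
    event_row("P3", "2005-03-10T08:00:00", "pht_free", 1.0, "mg/L"),
    # P4: albumin 8 days before the draw -> dropped
    event_row("P4", "2005-03-02T08:00:00", "albumin", 3.5, "g/dL"),
    event_row("P4", "2005-03-10T08:00:00", "pht_total", 15, "mg/L"),
    event_row("P4", "2005-03-10T08:00:00", "pht_free", 1.8, "mg/L"),
    # P5: total and free a day apart -> no pair
    event_row("P5", "2005-03-10T08:00:00", "pht_total", 14, "mg/L"),
    event_row("P5", "2005-03-11T08:00:00", "pht_free", 1.5, "mg/L")
  )
  write_event_csv(rows)
}

noise_free_config <- function(seed = 20, n = 756) {
  cohort_config(n_patients = n, binding_sd = 0, assay_cv_total = 0,
                assay_cv_free = 0, assay_cv_albumin = 0, seed = seed)
}

random_ct2 <- function(n_max = 30) {
  n <- sample(4:n_max, 1)
  repeat {
    cells <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
    m <- matrix(cells, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
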