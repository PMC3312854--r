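#' Configuration of the synthetic phenytoin-monitoring cohort
#'
#' Parameterizes a generative model for paired total/free phenytoin and
#' albumin lab events with the covariate structure of a large
#' retrospective hospital monitoring population: mostly adult
#' inpatients, hypoalbuminemia concentrated in inpatient and ICU strata,
#' albumin measured up to seven days before the phenytoin draw, and
#' repeat measurements for many patients.
#'
#' The generative binding model is deliberately consistent with the
#' albumin correction: each patient's true free fraction is
#' `min(1, 0.1 * exp(eta) / (0.2 * albumin + 0.1))` with
#' patient-level binding noise `eta ~ Normal(0, binding_sd)`, so with
#' `binding_sd = 0` and no assay noise the adjustment recovers the free
#' concentration exactly — the configuration under which parameter
#' recovery is checked. Assay noise is multiplicative,
#' `measured = true * (1 + CV * z)`.
#'
#' Repeat draws: `round(n_patients * repeat_measure_rate)` extra draws
#' are allocated across patients at random (multinomially), so the total
#' observation count is fixed by the configuration. Each later draw
#' multiplies the patient's total concentration by a lognormal
#' dose-drift factor, reflecting dose changes between draws.
#'
#' @param n_patients Number of patients.
#' @param repeat_measure_rate Expected extra draws per patient beyond
#'   the first.
#' @param sex_ratio Proportion of male patients.
#' @param location_weights Named probabilities over the six location
#'   strata (`adult_inpatient`, `peds_inpatient`, `icu`, `emergency`,
#'   `primary_care`, `other_outpatient`).
#' @param age_bands Data frame with columns `lower`, `upper`, `weight`
#'   (years; uniform within band).
#' @param albumin_mean_by_location Named mean plasma albumin (g/dL) per
#'   location stratum.
#' @param albumin_sd Between-patient albumin SD (g/dL); albumin is
#'   truncated to (1, 6) g/dL.
#' @param total_log_mean,total_log_sd Lognormal parameters of the true
#'   total phenytoin concentration (mg/L scale).
#' @param binding_sd SD of the patient-level log binding multiplier eta.
#' @param assay_cv_total,assay_cv_free,assay_cv_albumin Fractional
#'   assay coefficients of variation.
#' @param comed_weights Probabilities over 0/1/2/3+ additional
#'   anti-epileptic drugs.
#' @param seizure24h_rate Proportion with a documented seizure within
#'   24 h of the first draw.
#' @param lag_days_weights Probabilities over albumin-to-phenytoin lags
#'   of 0..7 days.
#' @param dose_drift_sd SD of the log dose-drift multiplier applied at
#'   each repeat draw.
#' @param icu_binding_shift Additive shift to `eta` for ICU patients
#'   (default 0); a nonzero value creates the kind of inpatient binding
#'   misspecification seen in real cohorts.
#' @param start_date Earliest possible first draw (POSIXct, UTC).
#' @param span_days Days over which patients' first draws are spread.
#' @param seed Integer seed; generation is fully reproducible from the
#'   configuration.
#' @return A validated list of class `cohort_config`.
#' @seealso [default_config()], [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 756,
                          repeat_measure_rate = 997 / 756,
                          sex_ratio = 422 / 756,
                          location_weights = c(
                            adult_inpatient = 535, peds_inpatient = 29,
                            icu = 147, emergency = 10, primary_care = 8,
                            other_outpatient = 23) / 752,
                          age_bands = data.frame(
                            lower = c(0, 1, 15, 31, 60, 80),
                            upper = c(1, 15, 31, 60, 80, 95),
                            weight = c(20, 35, 57, 334, 246, 64) / 756),
                          albumin_mean_by_location = c(
                            adult_inpatient = 3.1, peds_inpatient = 3.4,
                            icu = 2.7, emergency = 3.8, primary_care = 4.2,
                            other_outpatient = 4.0),
                          albumin_sd = 0.55,
                          total_log_mean = log(12),
                          total_log_sd = 0.45,
                          binding_sd = 0.25,
                          assay_cv_total = 0.08,
                          assay_cv_free = 0.08,
                          assay_cv_albumin = 0.08,
                          comed_weights = c(371, 305, 67, 13) / 756,
                          seizure24h_rate = 263 / 756,
                          lag_days_weights = c(559, 290, 215, 190, 152,
                                               103, 112, 132) / 1753,
                          dose_drift_sd = 0.35,
                          icu_binding_shift = 0,
                          start_date = as.POSIXct("1996-08-01 08:00:00",
                                                  tz = "UTC"),
                          span_days = 4800,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, repeat_measure_rate = repeat_measure_rate,
    sex_ratio = sex_ratio, location_weights = location_weights,
    age_bands = age_bands,
    albumin_mean_by_location = albumin_mean_by_location,
    albumin_sd = albumin_sd, total_log_mean = total_log_mean,
    total_log_sd = total_log_sd, binding_sd = binding_sd,
    assay_cv_total = assay_cv_total, assay_cv_free = assay_cv_free,
    assay_cv_albumin = assay_cv_albumin, comed_weights = comed_weights,
    seizure24h_rate = seizure24h_rate,
    lag_days_weights = lag_days_weights, dose_drift_sd = dose_drift_sd,
    icu_binding_shift = icu_binding_shift, start_date = start_date,
    span_days = span_days, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Default cohort configuration
#'
#' The default parameterization emulates the demographic and covariate
#' marginals of the reference monitoring population: 756 patients (422
#' male), six location strata dominated by adult inpatients, the
#' six-band age distribution, 371/756 on phenytoin monotherapy, 263/756
#' with a seizure within 24 h, albumin-to-phenytoin lag weights
#' proportional to the observed 0..7-day counts, and an expected
#' 997/756 extra draws per patient so the cohort carries 1753
#' observations in total. Marginals are matched and covariates sampled
#' independently; the joint distribution is not constrained.
#'
#' @return A `cohort_config` with all defaults.
#' @export
default_config <- function() cohort_config()

location_levels <- c("adult_inpatient", "peds_inpatient", "icu",
                     "emergency", "primary_care", "other_outpatient")

validate_config <- function(cfg) {
  fail <- function(...) stop("invalid cohort config: ", ..., call. = FALSE)
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1 ||
      cfg$n_patients != round(cfg$n_patients)) {
    fail("`n_patients` must be a positive integer")
  }
  if (cfg$repeat_measure_rate < 0) fail("`repeat_measure_rate` must be >= 0")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) {
    fail("`sex_ratio` must lie in [0, 1]")
  }
  for (nm in c("location_weights", "comed_weights", "lag_days_weights")) {
    w <- cfg[[nm]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      fail("`", nm, "` must be non-negative and sum to 1")
    }
  }
  if (!identical(sort(names(cfg$location_weights)), sort(location_levels))) {
    fail("`location_weights` must name the six location strata")
  }
  if (!identical(sort(names(cfg$albumin_mean_by_location)),
                 sort(location_levels))) {
    fail("`albumin_mean_by_location` must name the six location strata")
  }
  if (length(cfg$lag_days_weights) != 8L) {
    fail("`lag_days_weights` must have 8 entries (lags 0..7)")
  }
  ab <- cfg$age_bands
  if (!all(c("lower", "upper", "weight") %in% names(ab)) ||
      any(ab$upper <= ab$lower) || any(ab$weight < 0) ||
      abs(sum(ab$weight) - 1) > 1e-8) {
    fail("`age_bands` must define bands with weights summing to 1")
  }
  for (nm in c("albumin_sd", "total_log_sd", "binding_sd", "assay_cv_total",
               "assay_cv_free", "assay_cv_albumin", "dose_drift_sd")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 0) {
      fail("`", nm, "` must be a single non-negative number")
    }
  }
  if (any(cfg$albumin_mean_by_location <= 1) ||
      any(cfg$albumin_mean_by_location >= 6)) {
    fail("albumin means must lie inside the (1, 6) g/dL truncation bounds")
  }
  invisible(cfg)
}

#' Write / read a cohort configuration as JSON
#'
#' @param config A `cohort_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns the validated `cohort_config`.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$start_date <- format(out$start_date, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  # named vectors must serialize as JSON objects, not bare arrays
  out$location_weights <- as.list(out$location_weights)
  out$albumin_mean_by_location <- as.list(out$albumin_mean_by_location)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$start_date <- as.POSIXct(raw$start_date, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S")
  raw$location_weights <- unlist(raw$location_weights)
  raw$albumin_mean_by_location <- unlist(raw$albumin_mean_by_location)
  raw$age_bands <- as.data.frame(lapply(raw$age_bands, as.numeric))
  do.call(cohort_config, raw)
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lower), upper))
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic monitoring cohort
#'
#' Samples patients, covariates, true concentrations and measured lab
#' events under a [cohort_config()]. Each observation emits three lab
#' events: total phenytoin and free phenytoin at the identical draw
#' timestamp, and an albumin result 0-7 whole days earlier (lag sampled
#' from the configured weights). Successive draws for a patient are at
#' least eight days apart, so each phenytoin pair has exactly one
#' albumin eligible under the seven-day lookback.
#'
#' @param config A `cohort_config`.
#' @return A list with
#'   \describe{
#'     \item{events}{lab-event tibble in the [read_lab_events()] layout}
#'     \item{covariates}{per-patient covariate tibble}
#'     \item{truth}{per-observation ground truth (`albumin_true`,
#'       binding multiplier `eta`, free fraction `fu`, `total_true`,
#'       `free_true`)}
#'   }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config()", call. = FALSE)
  }
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  patient_id <- sprintf("P%05d", seq_len(n))

  # --- covariates ------------------------------------------------------
  band <- sample.int(nrow(config$age_bands), n, replace = TRUE,
                     prob = config$age_bands$weight)
  age <- stats::runif(n, config$age_bands$lower[band],
                      config$age_bands$upper[band])
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
  location <- sample(names(config$location_weights), n, replace = TRUE,
                     prob = config$location_weights)
  seizure_24h <- stats::runif(n) < config$seizure24h_rate
  n_additional_aeds <- sample(0:3, n, replace = TRUE,
                              prob = config$comed_weights)
  covariates <- tibble::tibble(patient_id, age, sex, location, seizure_24h,
                               n_additional_aeds)

  # --- patient-level biology ------------------------------------------
  albumin_true <- rtruncnorm1(
    n, config$albumin_mean_by_location[location], config$albumin_sd,
    1.0, 6.0)
  eta <- stats::rnorm(n, 0, config$binding_sd) +
    ifelse(location == "icu", config$icu_binding_shift, 0)
  fu <- pmin(1, 0.1 * exp(eta) / (0.2 * albumin_true + 0.1))
  total_base <- stats::rlnorm(n, config$total_log_mean, config$total_log_sd)

  # --- draw schedule ---------------------------------------------------
  n_extra <- round(n * config$repeat_measure_rate)
  extras <- if (n_extra > 0) {
    as.integer(stats::rmultinom(1, n_extra, rep(1, n)))
  } else {
    integer(n)
  }
  n_draws <- 1L + extras
  first_offset <- floor(stats::runif(n, 0, config$span_days))

  pat_idx <- rep(seq_len(n), n_draws)
  draw_no <- sequence(n_draws)
  n_obs <- length(pat_idx)

  gaps <- 8 + stats::rpois(n_obs, 6)  # days between successive draws
  gaps[draw_no == 1L] <- 0
  day_offset <- stats::ave(gaps, pat_idx, FUN = cumsum) +
    first_offset[pat_idx]
  draw_time <- config$start_date + day_offset * 86400

  # --- concentrations --------------------------------------------------
  drift_step <- exp(stats::rnorm(n_obs, 0, config$dose_drift_sd))
  drift_step[draw_no == 1L] <- 1
  drift <- stats::ave(drift_step, pat_idx, FUN = cumprod)
  total_true <- total_base[pat_idx] * drift
  free_true <- fu[pat_idx] * total_true

  noise <- function(true, cv, floor_at = 0) {
    pmax(true * (1 + cv * stats::rnorm(length(true))), floor_at)
  }
  total_meas <- noise(total_true, config$assay_cv_total)
  free_meas <- noise(free_true, config$assay_cv_free)
  lag <- sample(0:7, n_obs, replace = TRUE, prob = config$lag_days_weights)
  alb_time <- draw_time - lag * 86400
  alb_meas <- noise(albumin_true[pat_idx], config$assay_cv_albumin,
                    floor_at = 0.1)

  events <- tibble::tibble(
    patient_id = rep(patient_id[pat_idx], each = 3L),
    timestamp = as.POSIXct(
      as.numeric(rbind(as.numeric(alb_time), as.numeric(draw_time),
                       as.numeric(draw_time))),
      origin = "1970-01-01", tz = "UTC"),
    analyte = rep(c("albumin", "pht_total", "pht_free"), n_obs),
    value = as.numeric(rbind(alb_meas, total_meas, free_meas)),
    unit = rep(c("g/dL", "mg/L", "mg/L"), n_obs)
  )

  truth <- tibble::tibble(
    patient_id = patient_id[pat_idx],
    draw_time = draw_time,
    albumin_true = albumin_true[pat_idx],
    eta = eta[pat_idx],
    fu = fu[pat_idx],
    total_true = total_true,
    free_true = free_true
  )

  list(events = events, covariates = covariates, truth = truth)
}

#' Parameter-recovery report against generator ground truth
#'
#' Joins linked observations back to the generator's ground truth and
#' summarizes how well each comparator recovers the true therapeutic
#' category and the identity relationship: concordance of the
#' albumin-adjusted and total/10 categories against the true free
#' concentration's category, and the estimated slope of measured free
#' on adjusted free (true value 1 under the generative model).
#'
#' @param truth Ground-truth tibble from [generate_cohort()].
#' @param obs Linked observations for the same cohort.
#' @return A list with `n`, `concordance_adj_vs_truth_pct`,
#'   `concordance_scaled_vs_truth_pct`, `slope_free_vs_adj`, and
#'   `true_slope` (= 1).
#' @export
truth_report <- function(truth, obs) {
  joined <- dplyr::inner_join(
    obs, truth, by = c("patient_id", "draw_time"))
  if (nrow(joined) != nrow(obs)) {
    stop("observation ids do not match the ground truth", call. = FALSE)
  }
  free_rng <- range_free()
  true_cat <- classify(joined$free_true, free_rng)
  adj <- sheiner_tozer_adjust(joined$pht_total, joined$albumin)
  adj_cat <- classify(adj, free_rng)
  scaled_cat <- classify(scale_total(joined$pht_total), free_rng)
  fit <- ols_fit(adj, joined$pht_free)
  list(
    n = nrow(joined),
    concordance_adj_vs_truth_pct =
      100 * mean(adj_cat == true_cat),
    concordance_scaled_vs_truth_pct =
      100 * mean(scaled_cat == true_cat),
    slope_free_vs_adj = fit$slope,
    true_slope = 1
  )
}
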