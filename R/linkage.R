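#' Read a lab-event file
#'
#' Lab events arrive as a CSV with columns `patient_id`, `timestamp`
#' (ISO-8601), `analyte` (one of `pht_total`, `pht_free`, `albumin`),
#' `value` (non-negative) and `unit`. Phenytoin values must be mg/L;
#' albumin may be reported in g/dL or g/L, and g/L values are converted
#' to g/dL by dividing by 10 using the explicit unit tag — magnitude is
#' never used to guess the unit, because a 10-fold albumin error inverts
#' the downstream clinical classification.
#'
#' Malformed rows are rejected with an error naming the offending data
#' rows (1-based, excluding the header).
#'
#' @param path Path to the CSV file.
#' @return A tibble of lab events with `timestamp` parsed to UTC POSIXct
#'   and albumin converted to g/dL (unit tag rewritten accordingly).
#' @export
read_lab_events <- function(path) {
  if (!file.exists(path)) {
    stop("lab-event file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("patient_id", "timestamp", "analyte", "value", "unit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("lab-event file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  ts <- parse_timestamp(raw$timestamp)
  val <- suppressWarnings(as.numeric(raw$value))

  problems <- character(0)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts) > 0L) {
    problems <- c(problems, paste0("row ", bad_ts, ": unparseable timestamp '",
                                   raw$timestamp[bad_ts], "'"))
  }
  bad_val <- which(is.na(val) | val < 0)
  if (length(bad_val) > 0L) {
    problems <- c(problems, paste0("row ", bad_val,
                                   ": value must be a non-negative number, got '",
                                   raw$value[bad_val], "'"))
  }
  known_analytes <- c("pht_total", "pht_free", "albumin")
  bad_an <- which(!raw$analyte %in% known_analytes)
  if (length(bad_an) > 0L) {
    problems <- c(problems, paste0("row ", bad_an, ": unknown analyte '",
                                   raw$analyte[bad_an], "'"))
  }
  ok_unit <- (raw$analyte %in% c("pht_total", "pht_free") & raw$unit == "mg/L") |
    (raw$analyte == "albumin" & raw$unit %in% c("g/dL", "g/L"))
  bad_unit <- which(raw$analyte %in% known_analytes & !ok_unit)
  if (length(bad_unit) > 0L) {
    problems <- c(problems, paste0("row ", bad_unit, ": unknown unit tag '",
                                   raw$unit[bad_unit], "' for analyte '",
                                   raw$analyte[bad_unit], "'"))
  }
  if (length(problems) > 0L) {
    stop("lab-event file '", path, "' has invalid rows:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  unit <- raw$unit
  gl <- raw$analyte == "albumin" & unit == "g/L"
  val[gl] <- val[gl] / 10
  unit[gl] <- "g/dL"

  tibble::tibble(patient_id = raw$patient_id, timestamp = ts,
                 analyte = raw$analyte, value = val, unit = unit)
}

parse_timestamp <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    need <- is.na(out)
    if (!any(need)) break
    out[need] <- as.POSIXct(strptime(x[need], fmt, tz = "UTC"))
  }
  out
}

#' Write lab events to CSV
#'
#' Inverse of [read_lab_events()]; timestamps are written as ISO-8601
#' UTC and values at full (shortest round-trip) precision.
#'
#' @param events Tibble of lab events.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lab_events <- function(events, path) {
  out <- events
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Link phenytoin pairs to eligible albumin results
#'
#' Pairs total and free phenytoin events measured at the identical
#' timestamp (the same blood draw), then joins each pair to the most
#' recent albumin measured at or before the draw and no more than
#' `window_days` days earlier (a lookback window: an albumin drawn after
#' the phenytoin is never used). Pairs with no eligible albumin are
#' dropped and counted. `lag_days` is the floor of the day difference
#' between the draw and its albumin, so it takes values 0 to
#' `window_days`.
#'
#' Deterministic resolutions for degenerate inputs, each counted in the
#' linkage log: duplicate same-timestamp results for one analyte keep the
#' first in input order; ties among equally recent albumins (identical
#' timestamps) keep the last in input order.
#'
#' @param events Tibble of lab events from [read_lab_events()] or
#'   [generate_cohort()].
#' @param covariates Per-patient covariate tibble with columns
#'   `patient_id`, `age`, `sex`, `location`, `seizure_24h`,
#'   `n_additional_aeds`; joined onto the linked observations. May be
#'   `NULL` to link without covariates.
#' @param window_days Albumin lookback window in days (default 7).
#' @return A tibble of linked observations (`patient_id`, `draw_time`,
#'   `pht_total`, `pht_free`, `albumin`, `lag_days`, `year`, covariates)
#'   with the linkage log attached as attribute `"linkage_log"`; see
#'   [linkage_log()].
#' @export
link_observations <- function(events, covariates = NULL, window_days = 7) {
  if (!is.numeric(window_days) || length(window_days) != 1L ||
      window_days < 0) {
    stop("`window_days` must be a single non-negative number", call. = FALSE)
  }
  ev <- dplyr::mutate(events, .row = dplyr::row_number())

  # duplicate same-draw phenytoin results: keep first in input order;
  # same-timestamp albumins are tie-resolved at the join instead
  pht <- dplyr::filter(ev, .data$analyte != "albumin")
  n_before <- nrow(pht)
  pht <- pht |>
    dplyr::arrange(.data$.row) |>
    dplyr::distinct(.data$patient_id, .data$timestamp, .data$analyte,
                    .keep_all = TRUE)
  n_dup <- n_before - nrow(pht)
  if (n_dup > 0L) {
    warning(n_dup, " duplicate same-draw phenytoin result(s) dropped ",
            "(kept first)", call. = FALSE)
  }

  totals <- dplyr::filter(pht, .data$analyte == "pht_total")
  frees <- dplyr::filter(pht, .data$analyte == "pht_free")
  albs <- dplyr::filter(ev, .data$analyte == "albumin")

  pairs <- dplyr::inner_join(
    dplyr::select(totals, "patient_id", "timestamp", pht_total = "value"),
    dplyr::select(frees, "patient_id", "timestamp", pht_free = "value"),
    by = c("patient_id", "timestamp")
  )
  n_unpaired <- (nrow(totals) - nrow(pairs)) + (nrow(frees) - nrow(pairs))

  # most recent albumin with draw - window <= t_alb <= draw;
  # tie at identical timestamps -> last in input order
  alb_tab <- dplyr::select(albs, "patient_id", alb_time = "timestamp",
                           albumin = "value", alb_row = ".row")
  n_alb_ties <- 0L
  linked <- dplyr::inner_join(pairs, alb_tab, by = "patient_id",
                              relationship = "many-to-many") |>
    dplyr::filter(.data$alb_time <= .data$timestamp,
                  as.numeric(.data$timestamp) - as.numeric(.data$alb_time) <=
                    window_days * 86400)
  if (nrow(linked) > 0L) {
    linked <- linked |>
      dplyr::group_by(.data$patient_id, .data$timestamp) |>
      dplyr::arrange(dplyr::desc(.data$alb_time), dplyr::desc(.data$alb_row),
                     .by_group = TRUE)
    tie_info <- dplyr::summarise(
      linked,
      n_tied = sum(.data$alb_time == .data$alb_time[1L]), .groups = "drop")
    n_alb_ties <- sum(tie_info$n_tied > 1L)
    if (n_alb_ties > 0L) {
      warning(n_alb_ties, " draw(s) had albumin ties at identical ",
              "timestamps; kept the last in input order", call. = FALSE)
    }
    linked <- dplyr::slice_head(linked, n = 1L) |> dplyr::ungroup()
  }
  n_dropped <- nrow(pairs) - nrow(linked)

  obs <- linked |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      draw_time = .data$timestamp,
      pht_total = .data$pht_total,
      pht_free = .data$pht_free,
      albumin = .data$albumin,
      lag_days = floor(
        (as.numeric(.data$timestamp) - as.numeric(.data$alb_time)) / 86400),
      year = as.integer(format(.data$timestamp, "%Y", tz = "UTC"))
    ) |>
    dplyr::arrange(.data$patient_id, .data$draw_time)

  if (!is.null(covariates)) {
    obs <- dplyr::left_join(obs, covariates, by = "patient_id")
  }

  log <- list(
    n_phenytoin_pairs = nrow(pairs),
    n_linked = nrow(obs),
    n_dropped_no_albumin = n_dropped,
    n_unpaired_phenytoin_events = n_unpaired,
    n_duplicate_results_dropped = n_dup,
    n_albumin_ties = n_alb_ties,
    window_days = window_days
  )
  attr(obs, "linkage_log") <- log
  obs
}

#' Retrieve the linkage log of a linked cohort
#'
#' @param obs Output of [link_observations()].
#' @return Named list of linkage counts (pairs formed, linked, dropped
#'   for missing albumin, duplicates resolved, albumin ties).
#' @export
linkage_log <- function(obs) {
  log <- attr(obs, "linkage_log")
  if (is.null(log)) stop("no linkage log attached", call. = FALSE)
  log
}

#' Keep only the chronologically first observation per patient
#'
#' Analyses of between-patient agreement use only each patient's first
#' phenytoin pair to avoid weighting heavily monitored patients. Ties at
#' the identical minimal draw time resolve to the first in input order.
#' The operation is idempotent.
#'
#' @param obs Linked-observation tibble.
#' @return One row per `patient_id`, the earliest `draw_time`.
#' @export
first_per_patient <- function(obs) {
  obs |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$draw_time, .data$.row, .by_group = TRUE) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".row")
}

#' Consecutive within-patient observation pairs
#'
#' For each patient with k >= 2 time-ordered observations, emits the
#' k - 1 adjacent (previous, next) pairs, so the total number of pairs
#' equals the number of observations minus the number of distinct
#' patients. Used for the stability analysis of repeat measurements.
#'
#' @param obs Linked-observation tibble.
#' @return A tibble with the previous observation's columns prefixed
#'   `prev_` and the next observation's prefixed `next_`, plus
#'   `patient_id`.
#' @export
consecutive_pairs <- function(obs) {
  keep <- c("draw_time", "pht_total", "pht_free", "albumin", "lag_days")
  keep <- intersect(keep, names(obs))
  ordered <- obs |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$patient_id, .data$draw_time, .data$.row)
  prev <- ordered |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice(-dplyr::n()) |>
    dplyr::ungroup()
  nxt <- ordered |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice(-1L) |>
    dplyr::ungroup()
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = prev$patient_id),
    stats::setNames(prev[keep], paste0("prev_", keep)),
    stats::setNames(nxt[keep], paste0("next_", keep))
  )
  out
}

#' Write and read a linked cohort
#'
#' CSV round trip at full precision: `read_cohort(write_cohort(x))`
#' reproduces every field exactly (timestamps as ISO-8601 UTC, numerics
#' via shortest round-trip formatting).
#'
#' @param obs Linked-observation tibble.
#' @param path Output path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort`
#'   returns the tibble.
#' @export
write_cohort <- function(obs, path) {
  out <- obs
  if ("draw_time" %in% names(out)) {
    out$draw_time <- format(out$draw_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("draw_time" %in% names(obs)) {
    obs$draw_time <- as.POSIXct(obs$draw_time, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%S")
  }
  if ("seizure_24h" %in% names(obs)) {
    obs$seizure_24h <- as.logical(obs$seizure_24h)
  }
  obs
}
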