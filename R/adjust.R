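#' Adjustment coefficients for the albumin correction
#'
#' The albumin correction estimates the free (unbound) phenytoin
#' concentration from a total phenytoin measurement and a plasma albumin
#' result. Its canonical coefficients are a slope of 0.2 per g/dL albumin,
#' an intercept of 0.1, and a divisor of 10 (the assumed 10% free fraction
#' at normal albumin). They are configurable for sensitivity analyses but
#' default-locked to the published values; no renal-failure variant is
#' provided.
#'
#' @param slope_coeff Multiplier on albumin in the binding denominator,
#'   per (g/dL). Default 0.2.
#' @param intercept_coeff Dimensionless intercept of the binding
#'   denominator. Default 0.1.
#' @param free_fraction_divisor Divisor mapping the corrected total onto
#'   the free-concentration scale. Default 10 (a 10% free fraction).
#' @return A list of class `pht_coeffs` with the three components.
#' @examples
#' adjustment_coefficients()
#' @export
adjustment_coefficients <- function(slope_coeff = 0.2,
                                    intercept_coeff = 0.1,
                                    free_fraction_divisor = 10) {
  for (nm in c("slope_coeff", "intercept_coeff", "free_fraction_divisor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  structure(
    list(slope_coeff = slope_coeff,
         intercept_coeff = intercept_coeff,
         free_fraction_divisor = free_fraction_divisor),
    class = "pht_coeffs"
  )
}

check_coeffs <- function(coeffs) {
  if (!inherits(coeffs, "pht_coeffs")) {
    stop("`coeffs` must be created by adjustment_coefficients()", call. = FALSE)
  }
  invisible(coeffs)
}

#' Albumin-adjusted free phenytoin
#'
#' Computes the adjusted free phenytoin concentration
#' \deqn{C_{adj,free} = \frac{C_{total} / (0.2 \cdot \mathrm{Alb} + 0.1)}{10}}
#' with phenytoin concentrations in mg/L and albumin in g/dL. At the
#' reference albumin of 4.5 g/dL the denominator is exactly 1, so the
#' adjustment reduces to dividing the total concentration by 10.
#'
#' Vectorized over `total` and `albumin` (recycled to a common length).
#' No rounding is performed; present rounded values only at the reporting
#' layer.
#'
#' @param total Total phenytoin concentration(s), mg/L, non-negative.
#' @param albumin Plasma albumin concentration(s), g/dL, strictly positive.
#' @param coeffs Coefficients from [adjustment_coefficients()].
#' @return Adjusted free phenytoin concentration(s), mg/L.
#' @examples
#' sheiner_tozer_adjust(10, 4.5)  # 1.0 at reference albumin
#' sheiner_tozer_adjust(15, 2.0)  # hypoalbuminemia raises the estimate
#' @seealso [scale_total()], [implied_free_fraction()]
#' @export
sheiner_tozer_adjust <- function(total, albumin,
                                 coeffs = adjustment_coefficients()) {
  check_coeffs(coeffs)
  total <- check_concentration(total, "total")
  albumin <- check_albumin(albumin)
  total / (coeffs$slope_coeff * albumin + coeffs$intercept_coeff) /
    coeffs$free_fraction_divisor
}

#' Free fraction implied by the albumin correction
#'
#' The albumin correction is algebraically equivalent to assuming a free
#' fraction \eqn{f_u(\mathrm{Alb}) = 0.1 / (0.2 \cdot \mathrm{Alb} + 0.1)}
#' (with default coefficients): 10% of drug unbound at albumin 4.5 g/dL,
#' rising toward 1 as albumin falls to zero. The synthetic cohort
#' generator uses this as its generative binding model, which makes the
#' adjustment the correctly specified estimator on generated data.
#'
#' @inheritParams sheiner_tozer_adjust
#' @return Free fraction(s) in (0, 1].
#' @examples
#' implied_free_fraction(4.5)  # 0.1
#' implied_free_fraction(2.0)  # 0.2
#' @export
implied_free_fraction <- function(albumin,
                                  coeffs = adjustment_coefficients()) {
  check_coeffs(coeffs)
  albumin <- check_albumin(albumin)
  coeffs$intercept_coeff /
    (coeffs$slope_coeff * albumin + coeffs$intercept_coeff)
}

#' Total phenytoin on the free-concentration scale
#'
#' Divides total phenytoin by 10, the conventional mapping of the
#' 10-20 mg/L total therapeutic range onto the 1-2 mg/L free range under
#' an assumed 10% free fraction. This is the naive comparator the
#' albumin correction is evaluated against.
#'
#' @param total Total phenytoin concentration(s), mg/L, non-negative.
#' @return `total / 10`, mg/L on the free scale.
#' @examples
#' scale_total(14.3)
#' @export
scale_total <- function(total) {
  total <- check_concentration(total, "total")
  total / 10
}

check_concentration <- function(x, what) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("`", what, "` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`", what, "` must be finite and non-negative (mg/L)", call. = FALSE)
  }
  as.numeric(x)
}

check_albumin <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("`albumin` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("`albumin` must be finite and strictly positive (g/dL)",
         call. = FALSE)
  }
  as.numeric(x)
}

#' Therapeutic concentration ranges
#'
#' A therapeutic range is a closed concentration interval `[low, high]`
#' in mg/L. Values below `low` classify as `L`, values in the closed
#' interval as `T`, values above `high` as `H`. The closed-interval
#' convention means a result exactly at a published range edge counts as
#' within range.
#'
#' `range_total()` and `range_free()` return the usual phenytoin ranges:
#' 10-20 mg/L for total and 1-2 mg/L for free (and adjusted free)
#' concentrations.
#'
#' @param low Lower bound, mg/L, positive.
#' @param high Upper bound, mg/L, greater than `low`.
#' @param label Name used in reports.
#' @return A list of class `pht_range`.
#' @examples
#' range_free()
#' therapeutic_range(4, 12, "custom")
#' @export
therapeutic_range <- function(low, high, label = "range") {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high)) {
    stop("`low` and `high` must be single finite numbers", call. = FALSE)
  }
  if (low <= 0 || high <= low) {
    stop("require 0 < low < high", call. = FALSE)
  }
  structure(list(low = low, high = high, label = as.character(label)),
            class = "pht_range")
}

#' @rdname therapeutic_range
#' @export
range_total <- function() therapeutic_range(10, 20, "total phenytoin")

#' @rdname therapeutic_range
#' @export
range_free <- function() therapeutic_range(1, 2, "free phenytoin")

#' Therapeutic category levels, ordered L < T < H
#' @keywords internal
category_levels <- c("L", "T", "H")

#' Classify concentrations against a therapeutic range
#'
#' Assigns each concentration to `L` (below range), `T` (within the
#' closed interval), or `H` (above range). The three categories are
#' exhaustive and mutually exclusive for every finite non-negative value.
#'
#' @param conc Concentration(s), mg/L, non-negative.
#' @param range A [therapeutic_range()].
#' @return An ordered factor with levels `L < T < H`.
#' @examples
#' classify(c(0.5, 1.5, 2.5), range_free())
#' classify(20, range_total())  # boundary value is within range
#' @export
classify <- function(conc, range) {
  if (!inherits(range, "pht_range")) {
    stop("`range` must be created by therapeutic_range()", call. = FALSE)
  }
  conc <- check_concentration(conc, "conc")
  out <- ifelse(conc < range$low, "L", ifelse(conc > range$high, "H", "T"))
  factor(out, levels = category_levels, ordered = TRUE)
}
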