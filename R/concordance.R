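#' Three-by-three therapeutic-category contingency table
#'
#' Cross-tabulates the comparator method's therapeutic category (rows,
#' L/T/H) against the reference method's category (columns). In the
#' study design the measured free phenytoin is the reference and the
#' comparator is either total phenytoin (against its own 10-20 mg/L
#' range) or the albumin-adjusted free phenytoin (against the 1-2 mg/L
#' free range).
#'
#' @param comparator_cats,reference_cats Equal-length vectors of
#'   categories (`"L"`, `"T"`, `"H"`), e.g. from [classify()].
#' @param comparator_name,reference_name Labels carried into reports.
#' @return A 3x3 integer matrix of class `pht_ct3`, rows = comparator,
#'   columns = reference.
#' @examples
#' build_table(c("T", "T", "L"), c("T", "H", "L"))
#' @export
build_table <- function(comparator_cats, reference_cats,
                        comparator_name = "comparator",
                        reference_name = "reference") {
  if (length(comparator_cats) != length(reference_cats)) {
    stop("category sequences must have equal length", call. = FALSE)
  }
  if (length(comparator_cats) < 1L) {
    stop("cannot tabulate an empty category sequence", call. = FALSE)
  }
  comp <- factor(as.character(comparator_cats), levels = category_levels)
  ref <- factor(as.character(reference_cats), levels = category_levels)
  if (anyNA(comp) || anyNA(ref)) {
    stop("categories must be one of L, T, H", call. = FALSE)
  }
  counts <- table(comparator = comp, reference = ref)
  m <- matrix(as.integer(counts), nrow = 3L,
              dimnames = list(comparator = category_levels,
                              reference = category_levels))
  structure(m, class = c("pht_ct3", "matrix"),
            comparator_name = comparator_name,
            reference_name = reference_name)
}

#' @export
print.pht_ct3 <- function(x, ...) {
  cat("3x3 therapeutic-category table: ",
      attr(x, "comparator_name"), " (rows) vs ",
      attr(x, "reference_name"), " (columns), N = ", sum(x), "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Concordance summary of a 3x3 category table
#'
#' With the ordinal ordering L < T < H, an observation is *concordant*
#' when both methods assign the same category (the diagonal),
#' *under* when the comparator's category is ordinally below the
#' reference's (the comparator would suggest under-ranging and hence a
#' dose increase — clinical overdosing risk when acted on), and *over*
#' in the converse case. The three percentages sum to 100 exactly before
#' rounding.
#'
#' @param table A `pht_ct3` from [build_table()].
#' @return A list with `n`, `concordant_pct`, `under_pct`, `over_pct`
#'   (percent scale, unrounded) and the raw counts.
#' @export
summarize_table <- function(table) {
  if (!inherits(table, "pht_ct3")) {
    stop("`table` must be a pht_ct3 from build_table()", call. = FALSE)
  }
  n <- sum(table)
  if (n < 1L) stop("table has no observations", call. = FALSE)
  conc <- sum(diag(table))
  under <- table["L", "T"] + table["L", "H"] + table["T", "H"]
  over <- table["T", "L"] + table["H", "L"] + table["H", "T"]
  list(
    n = n,
    concordant = conc, under = under, over = over,
    concordant_pct = 100 * conc / n,
    under_pct = 100 * under / n,
    over_pct = 100 * over / n,
    comparator_name = attr(table, "comparator_name"),
    reference_name = attr(table, "reference_name")
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value for the 2x2 table `[[a, b], [c, d]]`, summing
#' hypergeometric probabilities of all tables (with the observed
#' margins) no more probable than the observed one. Used to compare the
#' concordant/discordant counts of two classification methods. If a row
#' or column margin is zero the association is undefined and p = 1 is
#' returned by convention, with a message.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  m <- matrix(as.integer(round(cells)), nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    message("fisher_exact_2x2: a margin is zero; returning p = 1")
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Pearson chi-squared test of independence
#'
#' Classical chi-squared statistic for an r x c count table with
#' df = (r-1)(c-1) and no continuity correction. An expected cell count
#' of zero (a zero margin) makes the statistic undefined and raises an
#' error naming the cell.
#'
#' @param table A count matrix (e.g. a `pht_ct3`) or anything coercible
#'   to one.
#' @return A list with `statistic`, `df`, and `p`.
#' @export
chi_squared <- function(table) {
  m <- unclass(as.matrix(table))
  if (any(m < 0) || sum(m) < 1) {
    stop("`table` must hold non-negative counts with N >= 1", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  zero <- which(expected == 0, arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    stop("expected count is zero in cell (", zero[1L, 1L], ",", zero[1L, 2L],
         "); chi-squared is undefined", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Compare two classification methods against one reference
#'
#' Builds the 2x2 table of concordant/discordant counts for each method
#' (versus the shared reference categories) and tests whether the
#' concordance rates differ: the headline statistic is Fisher's exact
#' test on that 2x2, as is conventional in method-comparison reports,
#' with the chi-squared test and - because the two methods classify the
#' same observations - McNemar's paired test reported alongside.
#'
#' @param cats_a,cats_b Category vectors for methods A and B.
#' @param ref_cats Reference category vector (same observations).
#' @param names_ab Length-2 character vector of method names.
#' @return A list with per-method concordant counts, `fisher_p`,
#'   `chi_squared` (list), and `mcnemar_p`.
#' @export
compare_methods <- function(cats_a, cats_b, ref_cats,
                            names_ab = c("A", "B")) {
  n <- length(ref_cats)
  if (length(cats_a) != n || length(cats_b) != n || n < 1L) {
    stop("all category vectors must share the same positive length",
         call. = FALSE)
  }
  agree_a <- as.character(cats_a) == as.character(ref_cats)
  agree_b <- as.character(cats_b) == as.character(ref_cats)
  tab <- matrix(c(sum(agree_a), sum(!agree_a), sum(agree_b), sum(!agree_b)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(method = names_ab,
                                c("concordant", "discordant")))
  mcn <- suppressWarnings(
    stats::mcnemar.test(table(factor(agree_a, c(FALSE, TRUE)),
                              factor(agree_b, c(FALSE, TRUE)))))
  list(
    counts = tab,
    concordant_pct = stats::setNames(100 * tab[, 1L] / n, names_ab),
    fisher_p = fisher_exact_2x2(tab[1L, 1L], tab[1L, 2L],
                                tab[2L, 1L], tab[2L, 2L]),
    chi_squared = chi_squared(tab),
    mcnemar_p = mcn$p.value
  )
}

#' Stability of therapeutic-category cells across consecutive draws
#'
#' For each within-patient consecutive pair of observations, the
#' previous and next draws each occupy a cell (comparator category,
#' reference category) of the 3x3 table; the stability rate is the
#' fraction of pairs whose cell is unchanged.
#'
#' @param prev_comp,prev_ref Categories of the earlier observation.
#' @param next_comp,next_ref Categories of the later observation.
#' @return A list with `agree`, `total`, and `pct`.
#' @export
stability_rate <- function(prev_comp, prev_ref, next_comp, next_ref) {
  n <- length(prev_comp)
  if (n < 1L) stop("no consecutive pairs supplied", call. = FALSE)
  if (length(prev_ref) != n || length(next_comp) != n ||
      length(next_ref) != n) {
    stop("category vectors must have equal length", call. = FALSE)
  }
  agree <- as.character(prev_comp) == as.character(next_comp) &
    as.character(prev_ref) == as.character(next_ref)
  list(agree = sum(agree), total = n, pct = 100 * sum(agree) / n)
}
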