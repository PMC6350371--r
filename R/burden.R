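#' Build a 2x2 case-control carrier contingency table
#'
#' The table underlying all burden statistics: `a` cases carrying a
#' qualifying variant, `b` reference individuals carrying one, `c` cases
#' without, `d` reference individuals without.
#'
#' @param a Cases carrying a qualifying variant.
#' @param b Reference individuals carrying a qualifying variant.
#' @param c Cases without a qualifying variant.
#' @param d Reference individuals without a qualifying variant.
#' @return An object of class `contingency_table`.
#' @examples
#' contingency_table(849, 672, 5263, 59797)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells))) stop("contingency table cells must not be NA")
  if (any(cells < 0)) stop("contingency table cells must be non-negative")
  if (any(cells != round(cells))) stop("contingency table cells must be integers")
  structure(as.list(cells), class = "contingency_table")
}

as_contingency_table <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.numeric(x) && length(x) == 4L) return(contingency_table(x[1], x[2], x[3], x[4]))
  stop("cannot interpret input as a 2x2 contingency table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("carrier", "non-carrier"), c("cases", "reference")))
  print(m)
  invisible(x)
}

# Haldane-Anscombe correction: +0.5 to every cell when any cell is zero.
# Returns numeric cells plus a flag; the Fisher test always uses raw counts.
ha_correct <- function(tab) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (all(cells == 0)) stop("all-zero contingency table: estimate undefined")
  if (tab$a + tab$b == 0) stop("no carriers in either cohort: estimate undefined")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(a = cells[1], b = cells[2], c = cells[3], d = cells[4], corrected = corrected)
}

#' Odds ratio of a 2x2 carrier table
#'
#' Computes OR = (a/b)/(c/d). If any cell is zero, 0.5 is added to all four
#' cells first (Haldane-Anscombe correction).
#'
#' @param table A [contingency_table()] (or numeric vector `c(a, b, c, d)`).
#' @return The odds ratio, a positive number.
#' @examples
#' odds_ratio(contingency_table(849, 672, 5263, 59797)) # 14.4
#' @export
odds_ratio <- function(table) {
  h <- ha_correct(as_contingency_table(table))
  (h$a / h$b) / (h$c / h$d)
}

# SE of ln(OR) on (possibly corrected) cells: sqrt(1/a + 1/b + 1/c + 1/d)
se_log_or <- function(h) sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)

# The method is defined with the conventional 1.96 multiplier at the 95%
# level; other levels fall back to the exact normal quantile.
z_multiplier <- function(level) {
  if (isTRUE(all.equal(level, 0.95))) 1.96
  else stats::qnorm(1 - (1 - level) / 2)
}

#' Confidence interval for the odds ratio
#'
#' Woolf (log) interval: exp(ln(OR) +/- z * SE), with
#' SE = sqrt(1/a + 1/b + 1/c + 1/d) and z = 1.96 at the default 95%
#' level. The zero-cell correction is applied identically to the point
#' estimate and the SE.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' or_confidence_interval(contingency_table(849, 672, 5263, 59797)) # 12.9-15.9
#' @export
or_confidence_interval <- function(table, level = 0.95) {
  h <- ha_correct(as_contingency_table(table))
  or <- (h$a / h$b) / (h$c / h$d)
  z <- z_multiplier(level)
  se <- se_log_or(h)
  c(low = exp(log(or) - z * se), high = exp(log(or) + z * se))
}

#' Etiological fraction from an odds ratio
#'
#' EF = (OR - 1)/OR: where the OR approximates the relative risk, the
#' proportion of exposed (variant-carrying) cases whose disease is
#' attributable to the exposure -- i.e. the probability that a rare variant
#' found in a patient with the disease is causative. Negative when OR < 1;
#' never clamped.
#'
#' @param or Odds ratio, a positive number (vectorised).
#' @return EF value(s) in (-Inf, 1).
#' @examples
#' etiological_fraction(20) # 0.95
#' @export
etiological_fraction <- function(or) {
  if (any(is.na(or)) || any(or <= 0)) stop("odds ratio must be positive")
  (or - 1) / or
}

#' Confidence interval for the etiological fraction
#'
#' Default `"delta"` method: EF +/- z * SE(ln OR)/OR, the delta-method
#' standard error of EF = 1 - 1/OR on the log-OR scale. The `"substitution"`
#' method instead transforms the OR interval endpoints through
#' EF = (OR - 1)/OR. Bounds are reported as computed (the upper bound may
#' exceed 1 for small tables, as printed in the source cohort tables).
#'
#' @inheritParams or_confidence_interval
#' @param method `"delta"` (default) or `"substitution"`.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' ef_confidence_interval(contingency_table(849, 672, 5263, 59797)) # 0.923-0.938
#' @export
ef_confidence_interval <- function(table, level = 0.95,
                                   method = c("delta", "substitution")) {
  method <- match.arg(method)
  h <- ha_correct(as_contingency_table(table))
  or <- (h$a / h$b) / (h$c / h$d)
  if (method == "substitution") {
    ci <- or_confidence_interval(table, level)
    return(c(low = (ci[[1]] - 1) / ci[[1]], high = (ci[[2]] - 1) / ci[[2]]))
  }
  half <- z_multiplier(level) * se_log_or(h) / or
  ef <- (or - 1) / or
  c(low = ef - half, high = ef + half)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability definition: conditioning on the table margins, the
#' p-value is the sum of hypergeometric probabilities of all tables as or
#' less probable than the observed one. Raw counts are used (no zero-cell
#' correction).
#'
#' @inheritParams odds_ratio
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(contingency_table(2, 0, 0, 2)) # 1/3
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- as_contingency_table(table)
  m <- tab$a + tab$c        # cases
  n <- tab$b + tab$d        # reference
  k <- tab$a + tab$b        # carriers
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab$a, m, n, k)
  # relative tolerance guards against ties lost to floating point
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Full burden estimate for one gene/variant-class stratum
#'
#' Builds the 2x2 table from carrier counts and cohort sizes and computes
#' the odds ratio, etiological fraction, their confidence intervals, the
#' two-sided Fisher exact p-value, and the case/reference carrier
#' frequencies.
#'
#' @param case_carriers Cases carrying a qualifying variant.
#' @param n_cases Total cases.
#' @param ref_carriers Reference individuals carrying a qualifying variant.
#' @param effective_ref_n Effective reference cohort size (see
#'   [effective_reference_n()] for the coverage adjustment).
#' @param level Confidence level for both intervals.
#' @param ef_method EF interval method, see [ef_confidence_interval()].
#' @return An object of class `association_estimate`: a list with elements
#'   `odds_ratio`, `or_ci`, `ef`, `ef_ci`, `p_value`, `case_freq`,
#'   `ref_freq`, `case_excess`, `zero_cell_corrected` and `table`.
#' @examples
#' burden_estimate(103, 6103, 86, 57018) # TNNT2 non-truncating: OR 11.4, EF 0.912
#' @export
burden_estimate <- function(case_carriers, n_cases, ref_carriers,
                            effective_ref_n, level = 0.95,
                            ef_method = c("delta", "substitution")) {
  ef_method <- match.arg(ef_method)
  if (n_cases < case_carriers) stop("n_cases must be >= case_carriers")
  if (effective_ref_n < ref_carriers) stop("effective_ref_n must be >= ref_carriers")
  tab <- contingency_table(case_carriers, ref_carriers,
                           n_cases - case_carriers,
                           effective_ref_n - ref_carriers)
  h <- ha_correct(tab)
  or <- (h$a / h$b) / (h$c / h$d)
  structure(list(
    odds_ratio = or,
    or_ci = or_confidence_interval(tab, level),
    ef = etiological_fraction(or),
    ef_ci = ef_confidence_interval(tab, level, ef_method),
    p_value = fisher_exact_two_sided(tab),
    case_freq = case_carriers / n_cases,
    ref_freq = ref_carriers / effective_ref_n,
    case_excess = case_carriers / n_cases - ref_carriers / effective_ref_n,
    zero_cell_corrected = h$corrected,
    table = tab
  ), class = "association_estimate")
}

#' @export
print.association_estimate <- function(x, digits_or = 1, digits_ef = 3, ...) {
  cat(sprintf("OR %s (%s-%s)  EF %s (%s-%s)  p = %.3g\n",
              format(round_half_away(x$odds_ratio, digits_or), nsmall = digits_or),
              format(round_half_away(x$or_ci[[1]], digits_or), nsmall = digits_or),
              format(round_half_away(x$or_ci[[2]], digits_or), nsmall = digits_or),
              format(round_half_away(x$ef, digits_ef), nsmall = digits_ef),
              format(round_half_away(x$ef_ci[[1]], digits_ef), nsmall = digits_ef),
              format(round_half_away(x$ef_ci[[2]], digits_ef), nsmall = digits_ef),
              x$p_value))
  cat(sprintf("case freq %.2f%% (%d/%d)  ref freq %.2f%% (%d/%d)%s\n",
              100 * x$case_freq, x$table$a, x$table$a + x$table$c,
              100 * x$ref_freq, x$table$b, x$table$b + x$table$d,
              if (x$zero_cell_corrected) "  [zero-cell corrected]" else ""))
  invisible(x)
}

#' Round half away from zero
#'
#' Fixed-precision rounding used when comparing against printed tables
#' (2.5 -> 3, -2.5 -> -3), unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @export
round_half_away <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Evaluate a variant-prioritisation method by partitioned burden
#'
#' Splits the carriers of a gene into those prioritised by a classifier
#' and the remainder, and computes a burden estimate for each partition.
#' A perfect discriminator drives the prioritised EF towards 1 (its case
#' frequency equals the case excess) and the remainder EF towards 0 (its
#' case frequency equals the population reference frequency).
#'
#' @param prioritised [contingency_table()] for the prioritised variants.
#' @param remainder [contingency_table()] for the remaining variants.
#' @param level Confidence level.
#' @return List with `association_estimate` elements `prioritised` and
#'   `remainder`; a partition with no carriers yields `NULL` for that side.
#' @export
classifier_partition_eval <- function(prioritised, remainder, level = 0.95) {
  p <- as_contingency_table(prioritised)
  r <- as_contingency_table(remainder)
  if (p$a + p$c != r$a + r$c || p$b + p$d != r$b + r$d)
    stop("partitions must share the same case and reference cohort totals")
  est <- function(t) {
    if (t$a + t$b == 0) return(NULL)
    burden_estimate(t$a, t$a + t$c, t$b, t$b + t$d, level)
  }
  list(prioritised = est(p), remainder = est(r))
}

#' Sensitivity, specificity and coverage of binary pathogenicity calls
#'
#' @param truth_labels Character vector of `"pathogenic"`/`"benign"` truth.
#' @param calls Character vector of `"damaging"`/`"benign"`/`"missing"`
#'   predictions, same length.
#' @return Named list `sensitivity` (damaging rate among pathogenic with a
#'   call), `specificity` (benign rate among benign with a call), and
#'   `coverage` (fraction with a non-missing call). A class with no
#'   non-missing calls yields `NA` for its rate.
#' @examples
#' sensitivity_specificity(c("pathogenic", "pathogenic", "benign", "benign"),
#'                         c("damaging", "missing", "benign", "damaging"))
#' @export
sensitivity_specificity <- function(truth_labels, calls) {
  if (length(truth_labels) != length(calls))
    stop("truth_labels and calls must have equal length")
  stopifnot(all(truth_labels %in% c("pathogenic", "benign")),
            all(calls %in% c("damaging", "benign", "missing")))
  ok <- calls != "missing"
  rate <- function(lab, call) {
    idx <- truth_labels == lab & ok
    if (!any(idx)) return(NA_real_)
    mean(calls[idx] == call)
  }
  list(sensitivity = rate("pathogenic", "damaging"),
       specificity = rate("benign", "benign"),
       coverage = mean(ok))
}

#' Consensus of several binary predictor calls
#'
#' Consensus is damaging when more than 50% of the predictors that made a
#' call predict a damaging effect, benign otherwise; missing when no
#' predictor made a call.
#'
#' @param calls Character vector of `"damaging"`/`"benign"`/`"missing"`.
#' @return `"damaging"`, `"benign"` or `"missing"`.
#' @export
consensus_call <- function(calls) {
  stopifnot(all(calls %in% c("damaging", "benign", "missing")))
  n_called <- sum(calls != "missing")
  if (n_called == 0) return("missing")
  if (sum(calls == "damaging") > n_called / 2) "damaging" else "benign"
}
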