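#' Cross-tabulate a high-risk flag against a binary outcome
#'
#' The flag plays the role of the diagnostic test, the outcome the role of
#' the condition.
#'
#' @param flag Logical vector (test positive).
#' @param outcome Logical vector (condition present), same length.
#' @return A `confusion_table`: counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(flag, outcome) {
  assert_flag_vector(flag, "flag")
  assert_flag_vector(outcome, "outcome")
  assert_same_length(flag, outcome, "flag", "outcome")
  confusion_table(tp = sum(flag & outcome), fp = sum(flag & !outcome),
                  fn = sum(!flag & outcome), tn = sum(!flag & !outcome))
}

#' Build a confusion table from counts
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @return A `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be nonnegative integers.")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table>  n =", x$tp + x$fp + x$fn + x$tn, "\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(flag = c("high", "not"), outcome = c("yes", "no")))
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic performance metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)` and overall
#' accuracy `(tp+tn)/n`. A zero denominator yields `NA` (an explicitly
#' undefined cell), never 0.
#'
#' @param x A `confusion_table`, or a logical flag vector (then supply
#'   `outcome`).
#' @param outcome Logical outcome vector when `x` is a flag vector.
#' @return One-row tibble with the five metrics.
#' @export
#' @examples
#' diagnostic_metrics(confusion_table(tp = 30, fp = 90, fn = 70, tn = 810))
diagnostic_metrics <- function(x, outcome = NULL) {
  if (!inherits(x, "confusion_table")) x <- confusion(x, outcome)
  n <- x$tp + x$fp + x$fn + x$tn
  if (n == 0) abort("Empty confusion table.")
  tibble::tibble(
    sensitivity = safe_ratio(x$tp, x$tp + x$fn),
    specificity = safe_ratio(x$tn, x$tn + x$fp),
    ppv = safe_ratio(x$tp, x$tp + x$fp),
    npv = safe_ratio(x$tn, x$tn + x$fn),
    accuracy = (x$tp + x$tn) / n)
}

#' Concordance statistic (rank-based AUC)
#'
#' Probability that a randomly chosen outcome-positive subject has a higher
#' score than a randomly chosen outcome-negative subject, counting ties as
#' one half. Invariant under strictly monotone transforms of the score.
#'
#' @param score Numeric (or ordinal) vector.
#' @param outcome Logical vector, both classes present.
#' @return Proportion in \[0, 1\], or `NA` (with a warning) when only one
#'   outcome class is present.
#' @export
c_statistic <- function(score, outcome) {
  assert_flag_vector(outcome, "outcome")
  assert_same_length(score, outcome, "score", "outcome")
  if (anyNA(score)) abort("`score` must not contain missing values.")
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) {
    warn("Both outcome classes are required for a c-statistic.")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

new_paired_comparison <- function(metric, estimate_a, estimate_b, statistic,
                                  p_value, method, ...) {
  structure(list(metric = metric, estimate_a = estimate_a,
                 estimate_b = estimate_b, delta = estimate_a - estimate_b,
                 statistic = statistic, p_value = p_value, method = method, ...),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: a=%.4f b=%.4f delta=%+.4f p=%.4g (%s)\n",
              x$metric, x$estimate_a, x$estimate_b, x$delta, x$p_value, x$method))
  invisible(x)
}

#' Paired comparison of two sensitivities on the same subjects
#'
#' Both flags are evaluated on the same patients, so the comparison is
#' restricted to outcome-positive subjects and based on the discordant
#' counts (flagged by a only vs flagged by b only), i.e. McNemar's test on
#' the positive subset: exact binomial when the discordant total is below
#' 25, normal approximation otherwise. This is the paired design needed
#' when comparing two screening rules applied to one cohort.
#'
#' @param flag_a,flag_b Logical flags on the same subjects.
#' @param outcome Logical outcome with at least one positive.
#' @param exact_limit Discordant total below which the exact test is used
#'   (default 25).
#' @return A `paired_comparison` with estimates (the two sensitivities),
#'   `delta`, the discordant counts, test statistic and two-sided p-value.
#' @export
compare_sensitivity_paired <- function(flag_a, flag_b, outcome, exact_limit = 25) {
  assert_flag_vector(flag_a, "flag_a"); assert_flag_vector(flag_b, "flag_b")
  assert_flag_vector(outcome, "outcome")
  assert_same_length(flag_a, outcome, "flag_a", "outcome")
  assert_same_length(flag_b, outcome, "flag_b", "outcome")
  if (sum(outcome) == 0) {
    warn("No outcome-positive subjects; paired sensitivity comparison undefined.")
    return(new_paired_comparison("sensitivity", NA_real_, NA_real_, NA_real_,
                                 NA_real_, "undefined",
                                 n_discordant = 0L, n_positive = 0L))
  }
  a <- flag_a[outcome]; b <- flag_b[outcome]
  n_pos <- length(a)
  n10 <- sum(a & !b); n01 <- sum(!a & b)
  m <- n10 + n01
  if (m == 0) {
    return(new_paired_comparison("sensitivity", mean(a), mean(b), 0,
                                 1, "exact discordant-pair (McNemar)",
                                 n_discordant = 0L, n_positive = n_pos))
  }
  if (m < exact_limit) {
    p <- min(1, 2 * pbinom(min(n10, n01), m, 0.5))
    stat <- n10
    method <- "exact discordant-pair (McNemar)"
  } else {
    stat <- (n10 - n01) / sqrt(m)
    p <- 2 * pnorm(-abs(stat))
    method <- "asymptotic discordant-pair (McNemar)"
  }
  new_paired_comparison("sensitivity", mean(a), mean(b), stat, p, method,
                        n_discordant = m, n_positive = n_pos)
}

#' Paired comparison of two positive predictive values
#'
#' Estimates the relative PPV (PPV of flag a over PPV of flag b) on the same
#' subjects and tests `H0: log rPPV = 0` with a delta-method variance that
#' accounts for the overlap of the two flagged sets: the eight cells of the
#' (flag a, flag b, outcome) cross-classification are treated as one
#' multinomial and the gradient of
#' `log n_AD - log n_A - log n_BD + log n_B` is propagated through its
#' covariance. Agrees closely with a paired nonparametric bootstrap.
#'
#' @param flag_a,flag_b Logical flags on the same subjects (each with at
#'   least one positive call).
#' @param outcome Logical outcome vector.
#' @return A `paired_comparison` with the two PPVs, their difference
#'   (`delta`), the `ratio` (relative PPV), z statistic and two-sided
#'   p-value.
#' @export
compare_ppv_paired <- function(flag_a, flag_b, outcome) {
  assert_flag_vector(flag_a, "flag_a"); assert_flag_vector(flag_b, "flag_b")
  assert_flag_vector(outcome, "outcome")
  assert_same_length(flag_a, outcome, "flag_a", "outcome")
  assert_same_length(flag_b, outcome, "flag_b", "outcome")
  n_a <- sum(flag_a); n_b <- sum(flag_b)
  if (n_a == 0 || n_b == 0) {
    warn("A flag with zero positive calls has no PPV; comparison undefined.")
    return(new_paired_comparison("ppv", NA_real_, NA_real_, NA_real_, NA_real_,
                                 "undefined", ratio = NA_real_))
  }
  n_ad <- sum(flag_a & outcome); n_bd <- sum(flag_b & outcome)
  ppv_a <- n_ad / n_a; ppv_b <- n_bd / n_b
  ratio <- ppv_a / ppv_b
  if (n_ad == 0 || n_bd == 0) {
    warn("A flag with zero true positives; log relative PPV undefined.")
    return(new_paired_comparison("ppv", ppv_a, ppv_b, NA_real_, NA_real_,
                                 "undefined", ratio = ratio))
  }
  # eight multinomial cells over (a, b, outcome)
  cell_a <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  cell_b <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  cell_d <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  idx <- 1L + 4L * (!flag_a) + 2L * (!flag_b) + (!outcome)
  m <- tabulate(idx, nbins = 8)
  g <- (cell_a & cell_d) / n_ad - cell_a / n_a - (cell_b & cell_d) / n_bd + cell_b / n_b
  v <- sum(m * g^2)   # gradient has zero multinomial mean, so this is the variance
  log_ratio <- log(ratio)
  if (v <= 0) {
    stat <- 0
    p <- if (abs(log_ratio) < 1e-12) 1 else NA_real_
  } else {
    stat <- log_ratio / sqrt(v)
    p <- 2 * pnorm(-abs(stat))
  }
  new_paired_comparison("ppv", ppv_a, ppv_b, stat, p,
                        "delta-method on log relative PPV",
                        ratio = ratio, se_log_ratio = sqrt(max(v, 0)))
}
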