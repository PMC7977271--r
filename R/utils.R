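#' @importFrom rlang abort warn inform %||%
#' @importFrom stats quantile rnorm runif rpois rgamma rbinom pnorm qnorm
#'   pbinom median uniroot plogis setNames
NULL

# canonical ordered tier labels, lowest to highest
tier_levels <- c("low", "moderate", "high", "very_high")

assert_flag_vector <- function(x, name) {
  if (!is.logical(x)) abort(sprintf("`%s` must be a logical vector.", name))
  if (anyNA(x)) abort(sprintf("`%s` must not contain missing values.", name))
  invisible(x)
}

assert_same_length <- function(a, b, name_a, name_b) {
  if (length(a) != length(b)) {
    abort(sprintf("`%s` (%d) and `%s` (%d) must have equal length.",
                  name_a, length(a), name_b, length(b)))
  }
}

assert_proportion <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) abort(sprintf("`%s` must be %s.", name,
                         if (open) "strictly inside (0, 1)" else "in [0, 1]"))
  invisible(x)
}

#' Gini coefficient of a nonnegative vector
#'
#' Concentration index used to summarize how unevenly expenditures are
#' spread across patients: 0 means perfectly even, values near 1 mean a
#' small share of patients carries almost all spend.
#'
#' @param x Numeric vector of nonnegative values.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' gini(c(1, 1, 1, 1))   # 0
#' gini(c(0, 0, 0, 10))  # 0.75
gini <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be a nonnegative numeric vector.")
  }
  n <- length(x)
  if (n == 0 || sum(x) == 0) return(0)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * sum(xs))
}

#' Share of the total carried by the top fraction of a vector
#'
#' @param x Nonnegative numeric vector (e.g. follow-year expenditures).
#' @param top Fraction of observations counted as the "top" (default 0.10).
#' @return Proportion of `sum(x)` held by the `top` fraction with the
#'   largest values.
#' @export
top_share <- function(x, top = 0.10) {
  if (sum(x) <= 0) abort("`x` must have a positive total.")
  assert_proportion(top, "top", open = TRUE)
  k <- max(1L, round(top * length(x)))
  sum(sort(x, decreasing = TRUE)[seq_len(k)]) / sum(x)
}

#' Significance stars for a p-value
#'
#' Legend: `*` p < .05, `**` p < .01, `***` p < .001.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector of star strings ("" when p >= .05 or NA).
#' @export
significance_stars <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

# deterministic child seed, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 97003 * as.numeric(offset)) %% 2147483647)
}
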