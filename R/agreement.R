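#' Cross-tabulate two binary high-risk flags
#'
#' @param flag_a,flag_b Logical vectors of equal length, no missing values
#'   (e.g. practice high-risk flag and algorithmic high-risk flag on the
#'   same patients).
#' @return A `concordance_table`: counts `n_both_high`, `n_a_only`,
#'   `n_b_only`, `n_neither`, `n_total`.
#' @export
concordance <- function(flag_a, flag_b) {
  assert_flag_vector(flag_a, "flag_a")
  assert_flag_vector(flag_b, "flag_b")
  assert_same_length(flag_a, flag_b, "flag_a", "flag_b")
  concordance_table(
    n_both_high = sum(flag_a & flag_b),
    n_a_only = sum(flag_a & !flag_b),
    n_b_only = sum(!flag_a & flag_b),
    n_neither = sum(!flag_a & !flag_b))
}

#' Build a concordance table from counts
#'
#' Useful when only published counts, not patient-level flags, are
#' available.
#'
#' @param n_both_high,n_a_only,n_b_only,n_neither Nonnegative counts.
#' @return A `concordance_table`.
#' @export
concordance_table <- function(n_both_high, n_a_only, n_b_only, n_neither) {
  counts <- c(n_both_high, n_a_only, n_b_only, n_neither)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Concordance counts must be nonnegative integers.")
  }
  structure(list(n_both_high = n_both_high, n_a_only = n_a_only,
                 n_b_only = n_b_only, n_neither = n_neither,
                 n_total = sum(counts)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("<concordance_table>  n =", x$n_total, "\n")
  m <- matrix(c(x$n_both_high, x$n_a_only, x$n_b_only, x$n_neither), 2, 2,
              dimnames = list(a = c("high", "not"), b = c("high", "not")))
  print(m)
  invisible(x)
}

#' Overall percent agreement
#'
#' @param t A `concordance_table`.
#' @return Proportion of subjects on which the two flags agree.
#' @export
percent_agreement <- function(t) {
  stopifnot(inherits(t, "concordance_table"))
  if (t$n_total == 0) abort("Empty concordance table.")
  (t$n_both_high + t$n_neither) / t$n_total
}

#' Proportion flagged by both among those flagged by either
#'
#' @param t A `concordance_table`.
#' @return `n_both_high / (n_both_high + n_a_only + n_b_only)`, or `NA`
#'   (with a warning) when nobody is flagged by either.
#' @export
both_over_either <- function(t) {
  stopifnot(inherits(t, "concordance_table"))
  either <- t$n_both_high + t$n_a_only + t$n_b_only
  if (either == 0) {
    warn("No subject flagged by either rater; both/either proportion undefined.")
    return(NA_real_)
  }
  t$n_both_high / either
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} where
#' \eqn{p_o} is the observed percent agreement and \eqn{p_e} the expected
#' agreement from the marginal products. When both marginals are degenerate
#' (\eqn{p_e = 1}) kappa is 1 for perfect agreement and undefined (`NA`)
#' otherwise.
#'
#' @param t A `concordance_table`.
#' @return Kappa in \[-1, 1\], or `NA` when undefined.
#' @export
cohens_kappa <- function(t) {
  stopifnot(inherits(t, "concordance_table"))
  n <- t$n_total
  if (n == 0) abort("Empty concordance table.")
  po <- percent_agreement(t)
  pa1 <- (t$n_both_high + t$n_a_only) / n
  pb1 <- (t$n_both_high + t$n_b_only) / n
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (abs(1 - pe) < 1e-15) {
    if (abs(1 - po) < 1e-15) return(1)
    warn("Degenerate marginals with imperfect agreement; kappa undefined.")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Qualitative band for a kappa value
#'
#' Landis-Koch bands, closed on the right: below 0 "poor", \[0, .2\]
#' "slight", (.2, .4\] "fair", (.4, .6\] "moderate", (.6, .8\]
#' "substantial", (.8, 1\] "almost perfect".
#'
#' @param kappa Numeric vector in \[-1, 1\].
#' @return Character vector of band labels.
#' @export
#' @examples
#' kappa_band(c(0.26, 0.32, 1))
kappa_band <- function(kappa) {
  if (any(!is.na(kappa) & (kappa < -1 | kappa > 1))) {
    abort("`kappa` must lie in [-1, 1].")
  }
  bands <- c("slight", "fair", "moderate", "substantial", "almost perfect")
  out <- ifelse(kappa < 0, "poor",
                bands[pmax(1, ceiling(pmin(pmax(kappa, 1e-12), 1) / 0.2))])
  out[is.na(kappa)] <- NA_character_
  out
}

#' One-row agreement report for two flags
#'
#' @param flag_a,flag_b Logical vectors (same subjects).
#' @param comparison Label for the comparison (e.g. "practice vs HCC").
#' @return A one-row tibble: counts, percent agreement, kappa, band,
#'   either-high count and the both/either proportion.
#' @export
agreement_summary <- function(flag_a, flag_b, comparison = "a vs b") {
  t <- concordance(flag_a, flag_b)
  glance_row <- glance(t)
  dplyr::bind_cols(tibble::tibble(comparison = comparison), glance_row)
}

#' Full tier-by-tier cross-tabulation
#'
#' The 4x4 companion to the binary [concordance()] collapse, so agreement
#' can also be read tier by tier (e.g. "low in both" as the lowest-tier
#' cell rather than the not-high cell).
#'
#' @param tiers_a,tiers_b Tier factors/characters on the same subjects.
#' @return Long tibble with columns `tier_a`, `tier_b`, `n` (16 rows).
#' @export
tier_crosstab <- function(tiers_a, tiers_b) {
  assert_same_length(tiers_a, tiers_b, "tiers_a", "tiers_b")
  a <- factor(as.character(tiers_a), levels = tier_levels)
  b <- factor(as.character(tiers_b), levels = tier_levels)
  if (anyNA(a) || anyNA(b)) abort("Unknown tier label.")
  as_tibble_xtab <- as.data.frame(table(tier_a = a, tier_b = b))
  out <- tibble::as_tibble(as_tibble_xtab)
  names(out)[3] <- "n"
  out$n <- as.integer(out$n)
  out
}
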