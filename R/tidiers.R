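#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a concordance table into long counts
#'
#' @param x A `concordance_table`.
#' @param ... Unused.
#' @return Tibble with columns `cell`, `n`.
#' @method tidy concordance_table
#' @export
tidy.concordance_table <- function(x, ...) {
  tibble::tibble(
    cell = c("both_high", "a_only", "b_only", "neither"),
    n = c(x$n_both_high, x$n_a_only, x$n_b_only, x$n_neither))
}

#' One-row agreement summary of a concordance table
#'
#' @param x A `concordance_table`.
#' @param ... Unused.
#' @return One-row tibble: counts, `either_high`, `pct_agreement`,
#'   `both_over_either`, `kappa`, `band`.
#' @method glance concordance_table
#' @export
glance.concordance_table <- function(x, ...) {
  k <- suppressWarnings(cohens_kappa(x))
  tibble::tibble(
    n = x$n_total, both_high = x$n_both_high, a_only = x$n_a_only,
    b_only = x$n_b_only, neither = x$n_neither,
    either_high = x$n_both_high + x$n_a_only + x$n_b_only,
    pct_agreement = percent_agreement(x),
    both_over_either = suppressWarnings(both_over_either(x)),
    kappa = k, band = kappa_band(k))
}

#' Tidy a confusion table into long counts
#'
#' @param x A `confusion_table`.
#' @param ... Unused.
#' @return Tibble with columns `cell`, `n`.
#' @method tidy confusion_table
#' @export
tidy.confusion_table <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "fn", "tn"),
                 n = c(x$tp, x$fp, x$fn, x$tn))
}

#' One-row diagnostic summary of a confusion table
#'
#' @param x A `confusion_table`.
#' @param ... Unused.
#' @return One-row tibble with n and the five diagnostic metrics.
#' @method glance confusion_table
#' @export
glance.confusion_table <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n = x$tp + x$fp + x$fn + x$tn),
                   diagnostic_metrics(x))
}

#' Tidy a paired comparison
#'
#' @param x A `paired_comparison`.
#' @param ... Unused.
#' @return One-row tibble: metric, the two estimates, `delta` (and `ratio`
#'   for PPV comparisons), statistic, p-value, stars and method.
#' @method tidy paired_comparison
#' @export
tidy.paired_comparison <- function(x, ...) {
  out <- tibble::tibble(
    metric = x$metric, estimate_a = x$estimate_a, estimate_b = x$estimate_b,
    delta = x$delta, statistic = x$statistic, p_value = x$p_value,
    stars = significance_stars(x$p_value), method = x$method)
  if (!is.null(x$ratio)) out$ratio <- x$ratio
  out
}
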