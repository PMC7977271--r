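#' Fit size-matched tier cut-points from a score distribution
#'
#' Chooses three strictly increasing thresholds `c1 < c2 < c3` so that the
#' four tiers `score < c1` (low), `[c1, c2)` (moderate), `[c2, c3)` (high)
#' and `>= c3` (very high) match the target tier proportions as closely as
#' ties allow. Tied scores are never split across a boundary: all copies of
#' a value land in the same tier, so achieved proportions can deviate from
#' the targets on heavily tied data. Deterministic and auditable.
#'
#' @param scores Numeric vector with at least 4 distinct finite values.
#' @param target_proportions Four proportions summing to 1, ordered
#'   low, moderate, high, very high.
#' @return A `tier_cutpoints` object: list with `c1`, `c2`, `c3`,
#'   `target_proportions` and `achieved_proportions`.
#' @export
#' @examples
#' cp <- fit_cutpoints(1:100, c(.25, .25, .25, .25))
#' table(assign_tiers(1:100, cp))
fit_cutpoints <- function(scores, target_proportions = c(0.40, 0.30, 0.20, 0.10)) {
  if (!is.numeric(scores) || anyNA(scores) || any(!is.finite(scores))) {
    abort("`scores` must be a finite numeric vector without missing values.")
  }
  p <- as.numeric(target_proportions)
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("`target_proportions` must be four nonnegative values summing to 1.")
  }
  d <- sort(unique(scores))
  if (length(d) < 4) abort("Need at least 4 distinct score values to form 4 tiers.")
  n <- length(scores)
  # count of scores strictly below each candidate threshold (the distinct values)
  below <- cumsum(tabulate(match(scores, d), nbins = length(d)))
  below <- c(0, below[-length(below)])
  ks <- cumsum(p)[1:3] * n
  idx <- integer(3)
  prev <- 0L
  for (j in 1:3) {
    cand <- which(seq_along(d) > prev)
    if (length(cand) == 0) abort("Scores too heavily tied to form 4 nonempty tier boundaries.")
    best <- cand[which.min(abs(below[cand] - ks[j]))]
    idx[j] <- best
    prev <- best
  }
  cuts <- d[idx]
  tiers <- cut_scores(scores, cuts)
  structure(
    list(c1 = cuts[1], c2 = cuts[2], c3 = cuts[3],
         target_proportions = setNames(p, tier_levels),
         achieved_proportions = setNames(as.numeric(table(tiers)) / n, tier_levels)),
    class = "tier_cutpoints")
}

cut_scores <- function(scores, cuts) {
  factor(tier_levels[1L + (scores >= cuts[1]) + (scores >= cuts[2]) + (scores >= cuts[3])],
         levels = tier_levels, ordered = TRUE)
}

#' Assign risk tiers from fitted cut-points
#'
#' The rule is half-open: `score < c1` is low, `[c1, c2)` moderate,
#' `[c2, c3)` high, and `score >= c3` very high (a score exactly at `c3` is
#' very high).
#'
#' @param scores Numeric vector.
#' @param cutpoints A [fit_cutpoints()] result.
#' @return Ordered factor of tiers (`low < moderate < high < very_high`),
#'   same length and order as `scores`.
#' @export
assign_tiers <- function(scores, cutpoints) {
  stopifnot(inherits(cutpoints, "tier_cutpoints"))
  cut_scores(scores, c(cutpoints$c1, cutpoints$c2, cutpoints$c3))
}

#' @export
print.tier_cutpoints <- function(x, ...) {
  cat("<tier_cutpoints>\n")
  cat(sprintf("  thresholds: c1=%.4g  c2=%.4g  c3=%.4g\n", x$c1, x$c2, x$c3))
  cat("  achieved proportions:",
      paste(sprintf("%s=%.3f", names(x$achieved_proportions), x$achieved_proportions),
            collapse = "  "), "\n")
  invisible(x)
}

#' Flag the single highest tier as high risk
#'
#' @param tiers Factor or character vector of tier labels.
#' @return Logical vector, `TRUE` where the tier is `very_high`.
#' @export
high_risk_flag <- function(tiers) {
  as.character(tiers) == "very_high"
}

#' Expenditure threshold capturing a target share of total spend
#'
#' Returns the largest threshold `t` such that patients with expenditure
#' `>= t` jointly account for at least `target_share` of total expenditure
#' (equivalently, the smallest top-k prefix by descending expenditure that
#' reaches the share). Used to pick outcome cut-points so that the flagged
#' group carries roughly two thirds of total utilization.
#'
#' @param expenditures Nonnegative numeric vector with a positive total.
#' @param target_share Proportion of total spend in (0, 1].
#' @return The threshold in the same units as `expenditures`.
#' @export
#' @examples
#' select_expenditure_cutpoint(c(50, 30, 10, 5, 3, 1, 1), 2 / 3)  # 30
select_expenditure_cutpoint <- function(expenditures, target_share = 2 / 3) {
  if (!is.numeric(expenditures) || anyNA(expenditures) || any(expenditures < 0)) {
    abort("`expenditures` must be nonnegative with no missing values.")
  }
  total <- sum(expenditures)
  if (total <= 0) abort("Total expenditure must be positive.")
  if (!is.numeric(target_share) || target_share <= 0 || target_share > 1) {
    abort("`target_share` must be in (0, 1].")
  }
  pos <- sort(expenditures[expenditures > 0], decreasing = TRUE)
  k <- which(cumsum(pos) >= target_share * total * (1 - 1e-12))[1]
  pos[k]
}

#' Outcome dichotomization thresholds
#'
#' Defaults follow the convention of flagging roughly the top decile of a
#' primary-care panel: expenditures at or above $30,000, two or more ED
#' visits, and one or more hospitalization in a year. "Over $30,000" is
#' implemented inclusively (`>=`).
#'
#' @param expenditure_cut USD threshold (> 0).
#' @param ed_cut ED visit count threshold (> 0).
#' @param hosp_cut Hospitalization count threshold (> 0).
#' @return A named list of class `outcome_thresholds`.
#' @export
outcome_thresholds <- function(expenditure_cut = 30000, ed_cut = 2, hosp_cut = 1) {
  if (any(c(expenditure_cut, ed_cut, hosp_cut) <= 0)) {
    abort("All outcome thresholds must be positive.")
  }
  structure(list(expenditure_cut = expenditure_cut, ed_cut = ed_cut,
                 hosp_cut = hosp_cut), class = "outcome_thresholds")
}

#' Dichotomize utilization outcomes at fixed cut-points
#'
#' Adds logical columns `high_ed`, `high_hosp`, `high_expend` computed from
#' the chosen observation window's columns (`follow_*` or `prior_*`) with
#' inclusive thresholds.
#'
#' @param patients Data frame with the window's `*_ed`, `*_hosp`,
#'   `*_expend` columns.
#' @param thresholds An [outcome_thresholds()].
#' @param window `"follow"` (default; the prediction target year) or
#'   `"prior"` (the calibration year).
#' @return `patients` as a tibble with the three flag columns added.
#' @export
dichotomize <- function(patients, thresholds = outcome_thresholds(),
                        window = c("follow", "prior")) {
  window <- match.arg(window)
  stopifnot(inherits(thresholds, "outcome_thresholds"))
  patients <- tibble::as_tibble(patients)
  cols <- paste0(window, "_", c("ed", "hosp", "expend"))
  miss <- setdiff(cols, names(patients))
  if (length(miss) > 0) {
    abort(sprintf("Missing outcome column(s): %s", paste(miss, collapse = ", ")))
  }
  dplyr::mutate(patients,
    high_ed = .data[[cols[1]]] >= thresholds$ed_cut,
    high_hosp = .data[[cols[2]]] >= thresholds$hosp_cut,
    high_expend = .data[[cols[3]]] >= thresholds$expenditure_cut)
}
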