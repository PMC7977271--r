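#' Stratified performance summary of two flags against several outcomes
#'
#' For every stratum (e.g. risk-stratification approach, or perception of
#' the process) and every outcome, computes the practice flag's and the
#' algorithmic flag's diagnostic metrics, their difference
#' (practice minus algorithm) and paired p-values (discordant-pair test for
#' sensitivity, delta-method relative-PPV test for PPV). Empty strata are
#' kept and flagged rather than dropped.
#'
#' @param data Data frame holding the flag, outcome and stratum columns.
#' @param practice_col,hcc_col Names of the logical flag columns.
#' @param outcome_cols Named character vector of logical outcome columns,
#'   e.g. `c(ed = "high_ed", hosp = "high_hosp", expend = "high_expend")`.
#' @param stratum_col Name of the stratum label column, or `NULL` for a
#'   single stratum labelled "all".
#' @return A tibble with columns `stratum`, `n`, `outcome`, `metric`,
#'   `practice`, `hcc`, `delta`, `p_value`, `stars`, `empty`. Metrics are
#'   sensitivity, specificity, ppv, npv and accuracy; p-values are reported
#'   for sensitivity and ppv.
#' @export
stratified_summary <- function(data, practice_col = "practice_high",
                               hcc_col = "hcc_high",
                               outcome_cols = c(ed = "high_ed",
                                                hosp = "high_hosp",
                                                expend = "high_expend"),
                               stratum_col = NULL) {
  data <- tibble::as_tibble(data)
  cols <- c(practice_col, hcc_col, unname(outcome_cols), stratum_col)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  if (is.null(names(outcome_cols))) names(outcome_cols) <- outcome_cols
  strata <- if (is.null(stratum_col)) rep("all", nrow(data)) else as.character(data[[stratum_col]])
  levels <- unique(strata)

  rows <- purrr::map_dfr(levels, function(s) {
    d <- data[strata == s, ]
    purrr::map_dfr(names(outcome_cols), function(oc) {
      out_col <- outcome_cols[[oc]]
      if (nrow(d) == 0) {
        return(tibble::tibble(stratum = s, n = 0L, outcome = oc,
                              metric = c("sensitivity", "specificity", "ppv",
                                         "npv", "accuracy"),
                              practice = NA_real_, hcc = NA_real_,
                              delta = NA_real_, p_value = NA_real_,
                              stars = "", empty = TRUE))
      }
      fp <- d[[practice_col]]; fh <- d[[hcc_col]]; y <- d[[out_col]]
      mp <- diagnostic_metrics(fp, y)
      mh <- diagnostic_metrics(fh, y)
      p_sens <- suppressWarnings(compare_sensitivity_paired(fp, fh, y)$p_value)
      p_ppv <- suppressWarnings(compare_ppv_paired(fp, fh, y)$p_value)
      long <- tibble::tibble(
        stratum = s, n = nrow(d), outcome = oc,
        metric = names(mp),
        practice = unname(unlist(mp)),
        hcc = unname(unlist(mh)),
        p_value = NA_real_, empty = FALSE)
      long$delta <- long$practice - long$hcc
      long$p_value[long$metric == "sensitivity"] <- p_sens
      long$p_value[long$metric == "ppv"] <- p_ppv
      long$stars <- significance_stars(long$p_value)
      long[, c("stratum", "n", "outcome", "metric", "practice", "hcc",
               "delta", "p_value", "stars", "empty")]
    })
  })
  rows
}

#' Averages and ranges across strata
#'
#' Collapses a [stratified_summary()] to per-outcome, per-metric averages
#' with min-max ranges across strata (the "average (range)" presentation),
#' separately for the practice flag, the algorithmic flag and their
#' difference. Strata are weighted equally by default; set
#' `weight = "patients"` to weight by stratum size.
#'
#' @param summary A [stratified_summary()] result.
#' @param weight `"strata"` (unweighted mean across strata, default) or
#'   `"patients"` (stratum-size-weighted mean).
#' @return Tibble with per outcome x metric: `practice_mean`,
#'   `practice_min`, `practice_max`, `hcc_mean`, `hcc_min`, `hcc_max`,
#'   `delta_mean`.
#' @export
across_strata <- function(summary, weight = c("strata", "patients")) {
  weight <- match.arg(weight)
  summary <- dplyr::filter(summary, !.data$empty)
  summary |>
    dplyr::group_by(.data$outcome, .data$metric) |>
    dplyr::summarise(
      practice_mean = if (weight == "strata") mean(.data$practice)
                      else sum(.data$practice * .data$n) / sum(.data$n),
      practice_min = min(.data$practice), practice_max = max(.data$practice),
      hcc_mean = if (weight == "strata") mean(.data$hcc)
                 else sum(.data$hcc * .data$n) / sum(.data$n),
      hcc_min = min(.data$hcc), hcc_max = max(.data$hcc),
      delta_mean = if (weight == "strata") mean(.data$delta)
                   else sum(.data$delta * .data$n) / sum(.data$n),
      .groups = "drop")
}

#' Average difference in deltas between two strata
#'
#' For one metric, averages the practice-minus-algorithm delta over the
#' outcomes within each of two strata and returns the difference of those
#' averages (stratum x minus stratum y). Antisymmetric in x and y.
#'
#' @param summary A data frame with columns `stratum`, `outcome`, `metric`,
#'   `delta` (e.g. a [stratified_summary()] result, or a table built from
#'   published delta cells).
#' @param metric Metric name, e.g. `"sensitivity"`.
#' @param stratum_x,stratum_y Stratum labels to contrast.
#' @return A single number: `mean(delta | x) - mean(delta | y)`.
#' @export
mean_delta_difference <- function(summary, metric, stratum_x, stratum_y) {
  pick <- function(s) {
    rows <- summary[summary$stratum == s & summary$metric == metric, ]
    if (nrow(rows) == 0 || anyNA(rows$delta)) {
      abort(sprintf("Stratum '%s' lacks complete '%s' deltas.", s, metric))
    }
    mean(rows$delta)
  }
  pick(stratum_x) - pick(stratum_y)
}
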