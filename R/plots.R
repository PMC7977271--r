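#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_histogram
#'   geom_vline geom_point geom_errorbar facet_grid labs scale_fill_gradient
#'   position_dodge theme_minimal
#' @export
ggplot2::autoplot

#' Plot a 2x2 concordance table
#'
#' @param object A `concordance_table`.
#' @param ... Unused.
#' @return A ggplot: tile plot of the four cells with counts printed.
#' @method autoplot concordance_table
#' @export
autoplot.concordance_table <- function(object, ...) {
  d <- tibble::tibble(
    a = factor(c("high", "high", "not high", "not high"),
               levels = c("not high", "high")),
    b = factor(c("high", "not high", "high", "not high"),
               levels = c("not high", "high")),
    n = c(object$n_both_high, object$n_a_only, object$n_b_only,
          object$n_neither))
  ggplot(d, aes(x = .data$b, y = .data$a, fill = .data$n)) +
    geom_tile(colour = "grey30") +
    geom_text(aes(label = .data$n)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "flag B", y = "flag A", fill = "patients",
         title = "High-risk flag concordance") +
    theme_minimal()
}

#' Plot fitted tier cut-points over a score distribution
#'
#' @param object A `tier_cutpoints` result.
#' @param scores The score vector the cut-points were fitted on.
#' @param ... Unused.
#' @return A ggplot: score histogram with the three thresholds marked.
#' @method autoplot tier_cutpoints
#' @export
autoplot.tier_cutpoints <- function(object, scores, ...) {
  ggplot(tibble::tibble(score = scores), aes(x = .data$score)) +
    geom_histogram(bins = 60, fill = "grey75", colour = "grey45") +
    geom_vline(xintercept = c(object$c1, object$c2, object$c3),
               linetype = "dashed", colour = "firebrick") +
    labs(x = "risk score", y = "patients",
         title = "Tier cut-points",
         subtitle = sprintf("c1 = %.3g, c2 = %.3g, c3 = %.3g",
                            object$c1, object$c2, object$c3)) +
    theme_minimal()
}

#' Plot a stratified performance summary
#'
#' Dot plot of practice vs algorithmic metric values per stratum, faceted
#' by outcome and metric.
#'
#' @param summary A [stratified_summary()] result.
#' @param metrics Metrics to show (default sensitivity, ppv, accuracy).
#' @return A ggplot.
#' @export
plot_stratified_summary <- function(summary,
                                    metrics = c("sensitivity", "ppv", "accuracy")) {
  d <- summary |>
    dplyr::filter(.data$metric %in% metrics, !.data$empty) |>
    tidyr::pivot_longer(c("practice", "hcc"), names_to = "source",
                        values_to = "value")
  ggplot(d, aes(x = .data$stratum, y = .data$value, colour = .data$source)) +
    geom_point(position = position_dodge(width = 0.4), size = 2) +
    facet_grid(metric ~ outcome) +
    labs(x = NULL, y = "metric value", colour = NULL,
         title = "Diagnostic performance by stratum") +
    theme_minimal()
}
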