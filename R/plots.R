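#' Heatmap of a cross-classification table
#'
#' Tile plot of the 7 x 7 percentile cross-classification, filled by the
#' row percentage (the share of each first-score bin that lands in each
#' second-score bin) and labelled with counts. A perfectly concordant pair
#' would light only the diagonal.
#'
#' @param object A `prs_crosstab`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prs_crosstab <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$b_bin, y = .data$a_bin,
                                  fill = .data$row_pct)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(PRS_BIN_LEVELS)) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "row %") +
    ggplot2::labs(x = "percentile bin, second score",
                  y = "percentile bin, first score") +
    ggplot2::theme_minimal()
}

#' Dot-and-interval plot of the agreement statistics
#'
#' Point estimates with confidence intervals (where available) for every
#' statistic in a [concordance_report()].
#'
#' @param object A `prs_concordance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prs_concordance <- function(object, ...) {
  d <- tidy(object)
  d$statistic <- factor(d$statistic, levels = rev(d$statistic))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$statistic)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of two standardized scores
#'
#' Standardized score B against standardized score A with the top-`k_pct`
#' thresholds of each marked; the off-diagonal shaded corners are the
#' individuals called very high risk by one score but not the other.
#'
#' @param scores_a,scores_b `prs_scores` tibbles over the same individuals
#'   with a `standardized` column.
#' @param k_pct Tail to mark, in percent (default 1).
#' @return A ggplot object.
#' @export
plot_score_agreement <- function(scores_a, scores_b, k_pct = 1) {
  d <- tibble::tibble(a = scores_a$standardized, b = scores_b$standardized)
  qa <- quantile(d$a, 1 - k_pct / 100)
  qb <- quantile(d$b, 1 - k_pct / 100)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_vline(xintercept = qa, linetype = 2, color = "firebrick") +
    ggplot2::geom_hline(yintercept = qb, linetype = 2, color = "firebrick") +
    ggplot2::labs(
      x = sprintf("%s (standardized)", attr(scores_a, "score_id") %||% "A"),
      y = sprintf("%s (standardized)", attr(scores_b, "score_id") %||% "B")
    ) +
    ggplot2::theme_minimal()
}
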