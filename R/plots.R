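#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a calibration table
#'
#' Step plot of the fitted local likelihood ratio over the score range, on a
#' log scale, with the graded evidence cutoffs overlaid.
#'
#' @param object An `acmg_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.acmg_calibration <- function(object, ...) {
  iv <- object$intervals
  finite_lo <- min(iv$lower[is.finite(iv$lower)], na.rm = TRUE)
  finite_hi <- max(iv$upper[is.finite(iv$upper)], na.rm = TRUE)
  iv$lower[!is.finite(iv$lower)] <- finite_lo - 0.05 * (finite_hi - finite_lo)
  iv$upper[!is.finite(iv$upper)] <- finite_hi + 0.05 * (finite_hi - finite_lo)
  cuts <- object$cutoffs
  cut_df <- tibble::tibble(
    lr = c(cuts$pathogenic_lr, cuts$benign_lr),
    side = rep(c("PP3", "BP4"), each = 3),
    strength = rep(cuts$strength, 2)
  )
  ggplot2::ggplot(iv) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$lower, xend = .data$upper, y = .data$lr, yend = .data$lr
    ), linewidth = 1) +
    ggplot2::geom_hline(
      data = cut_df,
      ggplot2::aes(yintercept = .data$lr, colour = .data$side),
      linetype = "dashed"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "score", y = "local likelihood ratio",
                  colour = "evidence side") +
    ggplot2::theme_minimal()
}

#' Plot feature attributions
#'
#' Horizontal bars of mean absolute contribution for the top features,
#' coloured by feature category.
#'
#' @param attribution Tibble from [feature_attribution()].
#' @param top_n Number of features to show (default 20).
#' @return A ggplot.
#' @export
plot_attribution <- function(attribution, top_n = 20L) {
  d <- utils::head(attribution[order(attribution$rank), ], top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$mean_abs_contrib,
    y = stats::reorder(.data$feature, .data$mean_abs_contrib),
    fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |contribution|", y = NULL,
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot score distributions by class with the decision threshold
#'
#' @param predictions Tibble from [predict.vep_model()], joined with a
#'   `label` column (1 = damaging).
#' @param threshold Optional decision threshold to overlay.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(predictions, threshold = NULL) {
  d <- predictions[!is.na(predictions$score), , drop = FALSE]
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$score, fill = factor(.data$label)
  )) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "model score", y = "variants", fill = "label") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed", colour = "blue")
  }
  p
}

#' Plot a MAVE benchmark
#'
#' Per-study smooth-fit R-squared by tool, with the per-tool mean overlaid.
#'
#' @param benchmark Result list from [mave_benchmark()].
#' @return A ggplot.
#' @export
plot_mave_benchmark <- function(benchmark) {
  d <- benchmark$per_study[!benchmark$per_study$excluded, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tool, y = .data$r2)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 3) +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
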