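#' Plot feature importance as bar charts
#'
#' @param object An `ed_importance`.
#' @param ... Unused.
#' @return A ggplot: dynamic saliency and static attention panels.
#' @method autoplot ed_importance
#' @export
autoplot.ed_importance <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$score),
    y = .data$score, fill = .data$channel)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::labs(x = NULL, y = "importance",
                  title = sprintf("Feature importance (%s, n = %d)",
                                  object$scope, object$n_samples)) +
    ggplot2::theme_minimal()
}

#' Plot the vital-sign trajectories of an explained visit
#'
#' @param object An `ed_explanation` from [explain_visit()].
#' @param raw Plot on the raw clinical scale (default) or normalized.
#' @param ... Unused.
#' @return A ggplot with one panel per sign; the pad region is shaded.
#' @method autoplot ed_explanation
#' @export
autoplot.ed_explanation <- function(object, raw = TRUE, ...) {
  tr <- object$trace
  tr$y <- if (raw) tr$value_raw else tr$value
  pad_edge <- max(c(-24, tr$hour[!tr$pad][1] - 1), na.rm = TRUE)
  ggplot2::ggplot(tr, ggplot2::aes(.data$hour, .data$y)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = pad_edge,
                      ymin = -Inf, ymax = Inf, alpha = 0.1) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~sign, scales = "free_y") +
    ggplot2::labs(x = "hours before discharge", y = NULL,
                  title = sprintf("Visit %s - predicted probability %.3f",
                                  object$visit_id, object$prob)) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object The `history` tibble returned by
#'   [train_revisit_net()] (columns `epoch`, `train_loss`,
#'   `val_auprc`).
#' @param ... Unused.
#' @return A ggplot of validation AUPRC and training loss by epoch.
#' @export
plot_history <- function(object, ...) {
  df <- tidyr::pivot_longer(object, -"epoch", names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
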