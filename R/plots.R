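#' Plot the objective trace of a fitted model
#'
#' @param model A `dlcmf` model.
#' @return A ggplot object.
#' @export
plot_objective <- function(model) {
  df <- tidy.dlcmf(model)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "objective loss",
                  title = "Alternating-optimization objective trace")
}

#' Plot the ROC curve of an evaluation report
#'
#' @param report An `ecg_eval` report.
#' @return A ggplot object.
#' @export
plot_roc <- function(report) {
  ggplot2::ggplot(report$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false acceptance rate", y = "1 - false rejection rate",
                  title = sprintf("ROC (AUC = %.4f, EER = %.2f%%)",
                                  report$auc, report$eer))
}

#' Plot FAR and FRR against the acceptance threshold
#'
#' @param report An `ecg_eval` report.
#' @return A ggplot object.
#' @export
plot_far_frr <- function(report) {
  df <- report$curve
  long <- data.frame(threshold = rep(df$threshold, 2),
                     rate = c(df$far, df$frr),
                     which = rep(c("FAR", "FRR"), each = nrow(df)))
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$threshold, .data$rate,
                               colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = report$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "acceptance threshold (score)", y = "rate",
                  colour = NULL,
                  title = sprintf("FAR/FRR sweep (EER = %.2f%%)",
                                  report$eer))
}

#' @importFrom ggplot2 autoplot .data
#' @export
autoplot.ecg_eval <- function(object, ...) plot_roc(object)

#' @export
ggplot2::autoplot
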