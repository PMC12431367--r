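#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the objective trace of a fitted model
#'
#' @param x A `dlcmf` model.
#' @param ... Unused.
#' @return A tibble with columns `iteration` and `objective`.
#' @export
tidy.dlcmf <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective_trace),
                 objective = x$objective_trace)
}

#' One-row model summary
#'
#' @param x A `dlcmf` model.
#' @param ... Unused.
#' @return A one-row tibble: latent dimension, training size, subject
#'   count, iterations run and final objective.
#' @export
glance.dlcmf <- function(x, ...) {
  tibble::tibble(r = nrow(x$V), n = ncol(x$V), c = x$label_info$c,
                 iterations = length(x$objective_trace),
                 objective = x$objective_trace[length(x$objective_trace)])
}

#' Tidy the FAR/FRR threshold sweep of an evaluation report
#'
#' @param x An `ecg_eval` report.
#' @param ... Unused.
#' @return A tibble with columns `threshold`, `far`, `frr`.
#' @export
tidy.ecg_eval <- function(x, ...) {
  tibble::as_tibble(x$curve)
}

#' One-row evaluation summary
#'
#' @param x An `ecg_eval` report.
#' @param ... Unused.
#' @return A one-row tibble: accuracy (percent), EER (percent), AUC and
#'   protocol sizes.
#' @export
glance.ecg_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, eer = x$eer, auc = x$auc,
                 n_probe = x$n_probe, n_enroll = x$n_enroll, c = x$c)
}
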