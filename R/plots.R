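# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot LSTM training history
#'
#' Training (and, when a validation split was held out, validation) loss per
#' epoch, with validation accuracy on a second panel.
#'
#' @param object A `pet_lstm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pet_lstm <- function(object, ...) {
  hist <- tidy(object)
  losses <- tidyr::pivot_longer(
    hist[, c("epoch", "train_loss", "val_loss")],
    c("train_loss", "val_loss"), names_to = "series", values_to = "loss"
  )
  losses <- losses[!is.na(losses$loss), , drop = FALSE]
  ggplot2::ggplot(losses, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                       colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "weighted loss", colour = NULL,
                  title = "LSTM training history") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation measures
#'
#' One panel per measure with per-fold points and the fold mean, for a
#' single `pet_cv` or a named list of them (methods compared side by side).
#'
#' @param object A `pet_cv` or a named list of `pet_cv` objects.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pet_cv <- function(object, ...) {
  plot_cv_metrics(setNames(list(object), object$method %||% "method"))
}

#' @rdname autoplot.pet_cv
#' @param results A named list of `pet_cv` objects.
#' @export
plot_cv_metrics <- function(results) {
  df <- bind_rows(imap(results, function(cv, nm) {
    mutate(tidy(cv), method = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value,
                                   colour = .data$method)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.3) +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = "Cross-validated performance measures") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
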