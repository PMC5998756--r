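# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted LSTM: per-epoch training history
#'
#' @param x A `pet_lstm`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `train_loss`, `val_loss`,
#'   `val_accuracy`.
#' @export
tidy.pet_lstm <- function(x, ...) {
  x$history
}

#' @rdname tidy.pet_lstm
#' @return `glance()`: a one-row model summary.
#' @export
glance.pet_lstm <- function(x, ...) {
  p <- x$params
  last <- x$history[nrow(x$history), ]
  tibble(
    epochs = x$config$epochs, hidden_size = x$config$hidden_size,
    embed_dim = p$d, vocab_size = p$V,
    n_parameters = length(p$E) + length(p$W) + length(p$U) + length(p$b) +
      length(p$w_out) + 1L,
    l2_lambda = x$config$l2_lambda,
    w_pos = x$class_weights$w_pos, w_neg = x$class_weights$w_neg,
    train_loss = last$train_loss, val_accuracy = last$val_accuracy
  )
}

#' Tidy a logistic-regression baseline: one row per term
#'
#' @param x A `pet_logreg`.
#' @param ... Unused.
#' @export
tidy.pet_logreg <- function(x, ...) {
  tibble(term = x$terms %||% as.character(seq_along(x$coefficients)),
         estimate = x$coefficients)
}

#' @rdname tidy.pet_logreg
#' @export
glance.pet_logreg <- function(x, ...) {
  tibble(n_features = length(x$coefficients), C = x$C,
         intercept = x$intercept,
         n_nonzero = sum(x$coefficients != 0))
}

#' Tidy cross-validation results: per-fold measures in long format
#'
#' @param x A `pet_cv`.
#' @param ... Unused.
#' @return A tibble with columns `fold`, `metric`, `value`, `flagged`.
#' @export
tidy.pet_cv <- function(x, ...) {
  tidyr::pivot_longer(x$fold_metrics, dplyr::all_of(METRIC_NAMES),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.pet_cv
#' @return `glance()`: one row with the method name, fold count, and mean
#'   measures.
#' @export
glance.pet_cv <- function(x, ...) {
  add_column(x$means, method = x$method, k = nrow(x$fold_metrics),
             .before = 1)
}

#' Tidy a paired t-test result
#'
#' @param x A `pet_ttest`.
#' @param ... Unused.
#' @export
tidy.pet_ttest <- function(x, ...) {
  tibble(t_stat = x$t_stat, df = x$df, p_one_tail = x$p_one_tail,
         direction = x$direction, flag = x$flag)
}
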