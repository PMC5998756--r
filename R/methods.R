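# Train/predict contracts consumed by cross_validate(). Each contract is a
# list(name, fit, predict): fit() takes the training rows of the data tibble
# (columns id, label, + representation columns), predict() returns a tibble
# with `probability` and `label` aligned to the test rows.

#' Method contract: word-embedding + LSTM classifier
#'
#' Wraps the LSTM pipeline for [cross_validate()]. The data tibble must
#' carry a `tokens` list-column (see [tokenize_tweets()]); each training
#' fold is encoded against the supplied vocabulary/embedding and a fresh
#' LSTM is fitted.
#'
#' @param embedding A pretrained `pet_embedding` (typically trained on a
#'   separate unlabeled corpus).
#' @param max_len Fixed sequence length for encoding (default 48).
#' @param ... Passed on to [fit_pet_lstm()] (epochs, hidden_size, seed, ...).
#' @return A method contract for [cross_validate()].
#' @export
lstm_method <- function(embedding, max_len = 48L, ...) {
  stopifnot(inherits(embedding, "pet_embedding"))
  dots <- list(...)
  encode_df <- function(df) {
    encode_corpus(
      tibble(tweet_id = as.character(df$id), label = df$label,
             tokens = df$tokens),
      embedding$vocab, max_len = max_len
    )
  }
  list(
    name = "lstm",
    fit = function(train) {
      do.call(fit_pet_lstm, c(list(encode_df(train), embedding), dots))
    },
    predict = function(model, test) {
      predict(model, encode_df(test))
    }
  )
}

#' Method contract: bag-of-words + logistic regression
#'
#' The BoW vocabulary is rebuilt from each training fold only; test-fold
#' terms unseen in training are dropped, as they would be in deployment.
#'
#' @param C Inverse regularisation strength (default 1000).
#' @param seed Stored with each fold's model (default 0).
#' @param binary Presence indicators instead of counts.
#' @return A method contract for [cross_validate()].
#' @export
bow_method <- function(C = 1000, seed = 0L, binary = FALSE) {
  tok_df <- function(df) tibble(tweet_id = as.character(df$id),
                                tokens = df$tokens)
  list(
    name = "bow_logreg",
    fit = function(train) {
      X <- bow_vectorize(tok_df(train), binary = binary)
      fit_logreg(X, train$label, C = C, seed = seed)
    },
    predict = function(model, test) {
      predict(model, bow_project(tok_df(test), model$terms))
    }
  )
}

#' Method contract: conventional classifier on a feature table
#'
#' For data tibbles whose non-`id`/`label` columns are numeric engineered
#' features (supplied by the caller); see [external_feature_harness()] for
#' the supported classifiers and settings.
#'
#' @param classifier One of `"logreg"`, `"tree"`, `"knn"`, `"svm"`.
#' @param settings Named list of classifier settings overrides.
#' @return A method contract for [cross_validate()].
#' @export
feature_table_method <- function(classifier, settings = list()) {
  m <- feature_method(match.arg(classifier, c("logreg", "tree", "knn", "svm")),
                      settings)
  feat <- function(df) df[, setdiff(names(df), c("id", "label")), drop = FALSE]
  list(
    name = classifier,
    fit = function(train) m$fit(feat(train), as_binary_label(train$label)),
    predict = function(model, test) m$predict(model, feat(test))
  )
}
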