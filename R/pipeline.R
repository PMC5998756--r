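#' Fit the full PET-identification pipeline
#'
#' Convenience wrapper chaining every stage: corpus filtering, tokenisation,
#' optional phrase merging, vocabulary construction, skip-gram embedding
#' training, fixed-length encoding, and class-weighted LSTM fitting. The
#' vocabulary and embeddings are learned from the (typically much larger)
#' unlabeled corpus when one is supplied, mirroring the two-pipeline design
#' in which unsupervised feature learning replaces hand-engineered features;
#' otherwise the labeled corpus itself is used.
#'
#' @param tweets Labeled tweet tibble (columns `id`, `text`, `label`).
#' @param unlabeled Optional unlabeled tweet tibble for vocabulary /
#'   embedding training.
#' @param dim Embedding dimension (default 128).
#' @param hidden_size LSTM hidden width (default 128).
#' @param max_len Fixed sequence length (default 48).
#' @param min_count Vocabulary frequency cutoff (default 1).
#' @param window,embed_epochs,negatives Skip-gram settings (defaults 5, 50,
#'   5; the embedding pass count is high because the wrapper is designed for
#'   corpora far smaller than the web-scale collections on which a handful
#'   of passes suffices).
#' @param use_phrases Learn and apply bigram phrase merges (default `FALSE`).
#' @param discount,phrase_threshold Phrase-learning settings (defaults 5, 10).
#' @param seed Master seed for embedding and classifier training.
#' @param ... Passed on to [fit_pet_lstm()] (epochs, l2_lambda,
#'   val_fraction, ...).
#' @return A `pet_pipeline` object holding the fitted `model`, `vocab`,
#'   `embedding`, optional `phrases`, and the encoding settings; use
#'   [predict.pet_pipeline()] on new raw tweets.
#' @export
pet_pipeline <- function(tweets, unlabeled = NULL, dim = 128L,
                         hidden_size = 128L, max_len = 48L, min_count = 1L,
                         window = 5L, embed_epochs = 50L, negatives = 5L,
                         use_phrases = FALSE, discount = 5,
                         phrase_threshold = 10, seed = 0L, ...) {
  labeled_tok <- tokenize_tweets(filter_corpus(tweets))
  source_tok <- if (is.null(unlabeled)) {
    labeled_tok
  } else {
    tokenize_tweets(filter_corpus(unlabeled))
  }

  phrases <- NULL
  if (use_phrases) {
    phrases <- learn_phrases(source_tok, discount = discount,
                             threshold = phrase_threshold)
    source_tok <- apply_phrases(phrases, source_tok)
    labeled_tok <- apply_phrases(phrases, labeled_tok)
  }

  vocab <- build_vocabulary(source_tok, min_count = min_count)
  embedding <- train_embeddings(source_tok, vocab, dim = dim,
                                window = window, epochs = embed_epochs,
                                negatives = negatives, seed = seed)
  encoded <- encode_corpus(labeled_tok, vocab, max_len = max_len)
  model <- fit_pet_lstm(encoded, embedding, hidden_size = hidden_size,
                        seed = seed, ...)
  structure(
    list(model = model, vocab = vocab, embedding = embedding,
         phrases = phrases, max_len = as.integer(max_len),
         use_phrases = use_phrases),
    class = "pet_pipeline"
  )
}

#' @param object A `pet_pipeline`.
#' @param newdata Raw tweet tibble (columns `id`, `text`).
#' @param ... Passed to [predict.pet_lstm()] (e.g. `threshold`).
#' @rdname pet_pipeline
#' @export
predict.pet_pipeline <- function(object, newdata, ...) {
  tok <- tokenize_tweets(filter_corpus(newdata))
  if (object$use_phrases) tok <- apply_phrases(object$phrases, tok)
  enc <- encode_corpus(tok, object$vocab, max_len = object$max_len)
  predict(object$model, enc, ...)
}

#' @exportS3Method base::print
print.pet_pipeline <- function(x, ...) {
  cat(sprintf("<pet_pipeline> V = %d, dim = %d, max_len = %d, phrases: %s\n",
              vocab_size(x$vocab), x$embedding$dim, x$max_len,
              x$use_phrases))
  print(x$model)
  invisible(x)
}
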