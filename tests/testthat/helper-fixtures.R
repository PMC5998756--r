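# Fixtures built in code; no data files.

# Vocabulary over explicit terms (indices 2.. in the order given).
make_vocab <- function(terms) {
  petminer:::new_pet_vocab(c("pad", "unk", terms))
}

# Embedding with deterministic rows: row of index i (0-based) is
# i * (1, 2, ..., dim) / dim; pad row is zero by construction (i = 0).
make_embedding <- function(vocab, dim = 4) {
  V <- vocab_size(vocab)
  M <- outer(seq_len(V) - 1, seq_len(dim) / dim)
  rownames(M) <- vocab$terms
  petminer:::new_pet_embedding(M, vocab)
}

# One-hot embedding (V = dim): orthogonal geometry for similarity tests.
make_onehot_embedding <- function(vocab) {
  V <- vocab_size(vocab)
  M <- diag(V)
  M[1, 1] <- 0  # pad row zero
  rownames(M) <- vocab$terms
  petminer:::new_pet_embedding(M, vocab)
}

# Independent brute-force bigram scorer for the phrase-learning oracle.
brute_force_phrase_scores <- function(seqs, discount) {
  toks <- unlist(seqs)
  N <- length(toks)
  out <- list()
  for (s in seqs) {
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      key <- paste(s[i], s[i + 1])
      out[[key]] <- (out[[key]] %||% 0) + 1
    }
  }
  tibble::tibble(
    token_a = vapply(strsplit(names(out), " "), `[`, "", 1),
    token_b = vapply(strsplit(names(out), " "), `[`, "", 2),
    n_ab = unlist(out, use.names = FALSE)
  ) |>
    dplyr::mutate(score = unname(
      (n_ab - discount) * N /
        (vapply(token_a, function(t) sum(toks == t), 0, USE.NAMES = FALSE) *
           vapply(token_b, function(t) sum(toks == t), 0, USE.NAMES = FALSE))
    ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive O(n^2) AUC pair counting: the independent oracle.
brute_force_auc <- function(y, score) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small labeled corpus with a clean token signal, for classifier tests.
make_signal_corpus <- function(n = 200, seed = 1, order = FALSE,
                               odds = 10, rate = 0.4) {
  synth_labeled_corpus(synth_corpus_spec(
    n_tweets = n, pet_fraction = 0.3, signal_odds = odds, signal_rate = rate,
    order_sensitive = order, vocab_size = 50, mean_length = 8, seed = seed
  ))
}
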