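#' Train skip-gram word embeddings
#'
#' Learns dense term vectors over a tokenized corpus with the skip-gram
#' negative-sampling objective: each (center, context) token pair within the
#' window is contrasted against `negatives` noise tokens drawn from the
#' unigram distribution raised to the 3/4 power. Out-of-vocabulary tokens are
#' mapped to `unk` before training, so the `unk` vector is trained like any
#' other term; the `pad` row is frozen at zero (padding must contribute
#' nothing downstream). Training is single-threaded and driven by R's RNG,
#' so a fixed seed reproduces the matrix bit-for-bit.
#'
#' @param sequences Tokenized corpus (tibble with a `tokens` list-column, or
#'   a bare list of token vectors).
#' @param vocab A `pet_vocab` built from (a superset of) the corpus.
#' @param dim Embedding dimension (default 128).
#' @param window Context window half-width (default 5).
#' @param epochs Passes over the corpus (default 5).
#' @param negatives Noise samples per positive pair (default 5).
#' @param learning_rate Initial learning rate, decayed linearly to
#'   `min_learning_rate` over training (defaults 0.025 and
#'   `learning_rate / 100`).
#' @param min_learning_rate Final learning rate of the linear decay.
#' @param seed Integer seed.
#' @return A `pet_embedding`: the V x dim matrix of term vectors (row names
#'   are the vocabulary terms) bound to its vocabulary.
#' @export
train_embeddings <- function(sequences, vocab, dim = 128L, window = 5L,
                             epochs = 5L, negatives = 5L,
                             learning_rate = 0.025,
                             min_learning_rate = learning_rate / 100,
                             seed = 1L) {
  seqs <- token_list(sequences)
  stopifnot(inherits(vocab, "pet_vocab"), dim >= 2, window >= 1,
            epochs >= 1, negatives >= 1)
  idx <- map(seqs, function(tk) vocab_index(vocab, tk))
  idx <- idx[map_int(idx, length) > 0]
  if (length(idx) == 0) {
    abort("Empty corpus after vocabulary mapping: nothing to train on")
  }

  V <- vocab_size(vocab)
  counts <- tabulate(unlist(idx, use.names = FALSE) + 1L, nbins = V)
  noise <- counts^0.75
  noise[PAD_INDEX + 1L] <- 0

  vectors <- with_seed(seed, sgns_train_cpp(
    idx, V, as.integer(dim), as.integer(window), as.integer(epochs),
    as.integer(negatives), learning_rate, min_learning_rate, noise
  ))
  rownames(vectors) <- vocab$terms
  new_pet_embedding(vectors, vocab)
}

new_pet_embedding <- function(vectors, vocab) {
  stopifnot(is.matrix(vectors), nrow(vectors) == vocab_size(vocab),
            all(is.finite(vectors)))
  structure(list(vectors = vectors, vocab = vocab, dim = ncol(vectors)),
            class = "pet_embedding")
}

#' @exportS3Method base::print
print.pet_embedding <- function(x, ...) {
  cat(sprintf("<pet_embedding> %d terms x %d dims\n", nrow(x$vectors), x$dim))
  invisible(x)
}

#' Nearest terms in the embedding space
#'
#' Ranks vocabulary terms by cosine similarity to a query term, excluding the
#' query itself and the reserved `pad` / `unk` entries. Ties are broken by
#' vocabulary index. An inspection aid for checking what the vector space
#' learned.
#'
#' @param embedding A `pet_embedding`.
#' @param term Query term (must be in the vocabulary).
#' @param k Number of neighbours (capped at the number of eligible terms).
#' @return A tibble with columns `term` and `cosine`, best first.
#' @export
nearest_terms <- function(embedding, term, k = 10L) {
  stopifnot(inherits(embedding, "pet_embedding"))
  vocab <- embedding$vocab
  if (!term %in% vocab$terms) {
    abort(sprintf("Term '%s' is not in the vocabulary", term))
  }
  M <- embedding$vectors
  q <- M[term, ]
  eligible <- setdiff(seq_len(nrow(M)), c(PAD_INDEX, UNK_INDEX) + 1L)
  eligible <- eligible[vocab$terms[eligible] != term]
  if (length(eligible) == 0) return(tibble(term = character(), cosine = double()))

  qn <- sqrt(sum(q^2))
  rows <- M[eligible, , drop = FALSE]
  norms <- sqrt(rowSums(rows^2))
  cosine <- unname(as.vector(rows %*% q) / (norms * qn))
  cosine[!is.finite(cosine)] <- 0  # zero-norm rows count as orthogonal
  ord <- order(-cosine, eligible)
  take <- utils::head(ord, k)
  tibble(term = vocab$terms[eligible[take]], cosine = cosine[take])
}

cosine_similarity <- function(a, b) {
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Write / read embeddings in word2vec text format
#'
#' First line `"V d"`, then one line per term: the term followed by `d`
#' space-separated coordinates, in vocabulary-index order.
#'
#' @param embedding A `pet_embedding`.
#' @param path File path.
#' @param vocab For reading: the `pet_vocab` the file is bound to; if `NULL`
#'   a vocabulary is reconstructed from the file's term order (first two
#'   terms must be `pad` and `unk`).
#' @return `read_embeddings_w2v()` returns a `pet_embedding`;
#'   `write_embeddings_w2v()` returns `path` invisibly.
#' @export
write_embeddings_w2v <- function(embedding, path) {
  stopifnot(inherits(embedding, "pet_embedding"))
  M <- embedding$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(M), ncol(M)), con)
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(rownames(M)[i], paste(sprintf("%.9g", M[i, ]), collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_embeddings_w2v
#' @export
read_embeddings_w2v <- function(path, vocab = NULL) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  V <- hdr[1]; d <- hdr[2]
  if (length(lines) != V + 1) abort("Embedding file row count mismatch")
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  terms <- map_chr(parts, 1)
  M <- do.call(rbind, map(parts, function(p) as.numeric(p[-1])))
  if (ncol(M) != d) abort("Embedding file dimension mismatch")
  rownames(M) <- terms
  if (is.null(vocab)) {
    if (!identical(terms[1:2], c(PAD_TOKEN, UNK_TOKEN))) {
      abort("Embedding file must start with the reserved 'pad' and 'unk' rows")
    }
    vocab <- new_pet_vocab(terms)
  } else if (!identical(terms, vocab$terms)) {
    abort("Embedding file terms do not match the supplied vocabulary")
  }
  new_pet_embedding(M, vocab)
}
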