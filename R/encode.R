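#' Encode token sequences as fixed-length index sequences
#'
#' Maps each token to its vocabulary index (unknown tokens to `unk` = 1),
#' right-pads shorter sequences with `pad` = 0 to exactly `max_len`
#' positions, and tail-truncates longer ones. The pre-padding token count is
#' recorded as `true_length` (capped at `max_len`). The default `max_len` of
#' 48 matches the longest tweet the reference corpus design anticipates.
#'
#' @param sequences Tokenized corpus (tibble with `tweet_id` and `tokens`
#'   columns, or bare list of token vectors).
#' @param vocab A `pet_vocab`.
#' @param max_len Fixed sequence length (default 48).
#' @param on_long `"truncate"` (default) or `"error"` for sequences longer
#'   than `max_len`.
#' @return A `pet_encoded` tibble with columns `tweet_id`, `label` (if the
#'   input carried one), list-column `indices` (integer vectors of length
#'   `max_len`, 0-based), and `true_length`. The `max_len` and vocabulary
#'   size are stored as attributes.
#' @export
#' @examples
#' v <- build_vocabulary(list(c("thank", "you", "aspirin")))
#' enc <- encode_corpus(list(c("thank", "you", "xyz")), v, max_len = 5)
#' enc$indices[[1]]
encode_corpus <- function(sequences, vocab, max_len = 48L,
                          on_long = c("truncate", "error")) {
  on_long <- match.arg(on_long)
  stopifnot(inherits(vocab, "pet_vocab"), max_len >= 1)
  is_df <- is.data.frame(sequences)
  seqs <- token_list(sequences)

  enc <- map(seqs, encode_tokens, vocab = vocab, max_len = max_len,
             on_long = on_long)
  out <- tibble(
    tweet_id = if (is_df && "tweet_id" %in% names(sequences)) {
      as.character(sequences$tweet_id)
    } else {
      as.character(seq_along(seqs))
    },
    indices = map(enc, "indices"),
    true_length = map_int(enc, "true_length")
  )
  if (is_df && "label" %in% names(sequences)) {
    out <- add_column(out, label = sequences$label, .after = "tweet_id")
  }
  structure(out, class = c("pet_encoded", class(out)),
            max_len = as.integer(max_len), vocab_size = vocab_size(vocab))
}

#' Encode a single token vector
#'
#' Low-level worker behind [encode_corpus()].
#'
#' @inheritParams encode_corpus
#' @param tokens Character vector of tokens.
#' @return A list with `indices` (length `max_len`, 0-based) and
#'   `true_length`.
#' @export
encode_tokens <- function(tokens, vocab, max_len = 48L,
                          on_long = c("truncate", "error")) {
  on_long <- match.arg(on_long)
  idx <- vocab_index(vocab, tokens)
  n <- length(idx)
  if (n > max_len) {
    if (on_long == "error") {
      abort(sprintf("Sequence of length %d exceeds max_len %d", n, max_len))
    }
    idx <- idx[seq_len(max_len)]
  }
  list(
    indices = as.integer(c(idx, rep(PAD_INDEX, max_len - length(idx)))),
    true_length = as.integer(min(n, max_len))
  )
}

#' Decode an index sequence back to tokens
#'
#' Inverse of [encode_tokens()] up to unknown-token substitution and
#' truncation: pad positions are dropped, `unk` positions come back as the
#' literal `"unk"`.
#'
#' @param indices Integer vector of 0-based vocabulary indices.
#' @param vocab A `pet_vocab`.
#' @return Character vector of tokens.
#' @export
decode_tokens <- function(indices, vocab) {
  indices <- indices[indices != PAD_INDEX]
  vocab_term(vocab, indices)
}

#' Look up the dense vectors of an index sequence
#'
#' Row-wise gather from the embedding matrix: position `t` of the result is
#' the embedding row of `indices[t]`. Pad positions yield all-zero rows
#' (the pad embedding row is frozen at zero).
#'
#' @param indices Integer vector of 0-based indices (one encoded tweet), or a
#'   `pet_encoded` row's `indices[[i]]`.
#' @param embedding A `pet_embedding`.
#' @return A `length(indices)` x `dim` numeric matrix.
#' @export
lookup_vectors <- function(indices, embedding) {
  stopifnot(inherits(embedding, "pet_embedding"))
  V <- nrow(embedding$vectors)
  bad <- which(indices < 0L | indices >= V)
  if (length(bad)) {
    abort(sprintf("Index %d at position %d is outside the vocabulary (V = %d)",
                  indices[bad[1]], bad[1], V))
  }
  M <- embedding$vectors[indices + 1L, , drop = FALSE]
  rownames(M) <- NULL
  M
}

# Stack a pet_encoded tibble into an n x max_len integer matrix (0-based).
encoded_matrix <- function(encoded) {
  stopifnot(inherits(encoded, "pet_encoded"))
  do.call(rbind, encoded$indices)
}

#' Write / read encoded corpora as JSON-lines
#'
#' One JSON object per line with fields `id`, `indices`, `true_length`, and
#' optionally `label`.
#'
#' @param encoded A `pet_encoded` tibble.
#' @param path File path.
#' @param max_len For reading: expected sequence length (validated).
#' @return `read_encoded_jsonl()` returns a `pet_encoded` tibble.
#' @export
write_encoded_jsonl <- function(encoded, path) {
  stopifnot(inherits(encoded, "pet_encoded"))
  has_label <- "label" %in% names(encoded)
  lines <- vapply(seq_len(nrow(encoded)), function(i) {
    rec <- list(id = encoded$tweet_id[i],
                indices = encoded$indices[[i]],
                true_length = encoded$true_length[i])
    if (has_label && !is.na(encoded$label[i])) rec$label <- encoded$label[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_encoded_jsonl
#' @export
read_encoded_jsonl <- function(path, max_len = NULL) {
  lines <- readLines(path)
  recs <- map(lines, jsonlite::fromJSON)
  lens <- map_int(recs, function(r) length(r$indices))
  if (length(unique(lens)) > 1) abort("Inconsistent sequence lengths in file")
  if (!is.null(max_len) && lens[1] != max_len) {
    abort(sprintf("File sequences have length %d, expected %d", lens[1], max_len))
  }
  out <- tibble(
    tweet_id = map_chr(recs, function(r) as.character(r$id)),
    label = map_chr(recs, function(r) r$label %||% NA_character_),
    indices = map(recs, function(r) as.integer(r$indices)),
    true_length = map_int(recs, function(r) as.integer(r$true_length))
  )
  if (all(is.na(out$label))) out$label <- NULL
  structure(out, class = c("pet_encoded", class(out)),
            max_len = lens[1], vocab_size = NA_integer_)
}
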