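#' Build a term-index vocabulary
#'
#' Compiles the set of unique terms of a tokenized corpus into a vocabulary
#' mapping each term to a non-negative integer index. Index 0 is reserved for
#' the padding symbol `"pad"` and index 1 for the unknown-token symbol
#' `"unk"`; corpus terms with frequency at least `min_count` are assigned
#' indices from 2 upward, ordered by descending frequency with ties broken
#' lexicographically.
#'
#' Corpus tokens spelled exactly `"pad"` or `"unk"` would collide with the
#' reserved entries; they are excluded from the vocabulary (and therefore
#' encode as `unk`) with a warning.
#'
#' @param sequences A tokenized corpus tibble or list of token vectors.
#' @param min_count Minimum corpus frequency for a term to enter the
#'   vocabulary (default 1).
#' @return A `pet_vocab` object.
#' @export
#' @examples
#' v <- build_vocabulary(list(c("a", "a", "b")))
#' vocab_index(v, c("a", "b", "zzz"))  # 2 3 1 (unknown -> unk)
build_vocabulary <- function(sequences, min_count = 1L) {
  seqs <- token_list(sequences)
  stopifnot(min_count >= 1)
  tokens <- unlist(seqs, use.names = FALSE)
  if (length(tokens) == 0) {
    abort("Cannot build a vocabulary from an empty corpus")
  }
  freq <- table(tokens)
  if (any(names(freq) %in% c(PAD_TOKEN, UNK_TOKEN))) {
    warn(sprintf(
      "Corpus token(s) colliding with reserved entries ('%s'/'%s') excluded from the vocabulary",
      PAD_TOKEN, UNK_TOKEN
    ))
    freq <- freq[!names(freq) %in% c(PAD_TOKEN, UNK_TOKEN)]
  }
  freq <- freq[freq >= min_count]
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  kept <- names(freq)[ord]
  new_pet_vocab(c(PAD_TOKEN, UNK_TOKEN, kept),
                counts = c(NA_integer_, NA_integer_, as.integer(freq)[ord]))
}

new_pet_vocab <- function(terms, counts = NULL) {
  stopifnot(terms[1] == PAD_TOKEN, terms[2] == UNK_TOKEN,
            !anyDuplicated(terms))
  structure(
    list(
      terms = terms,
      index = setNames(seq_along(terms) - 1L, terms),  # 0-based
      counts = counts
    ),
    class = "pet_vocab"
  )
}

#' Vocabulary size (including the two reserved entries)
#' @param vocab A `pet_vocab`.
#' @export
vocab_size <- function(vocab) {
  stopifnot(inherits(vocab, "pet_vocab"))
  length(vocab$terms)
}

#' Map terms to vocabulary indices
#'
#' Unknown terms map to the `unk` index (1). Indices are 0-based, matching
#' the on-disk representation (`pad` = 0, `unk` = 1).
#'
#' @param vocab A `pet_vocab`.
#' @param terms Character vector of terms.
#' @return Integer vector of indices.
#' @export
vocab_index <- function(vocab, terms) {
  stopifnot(inherits(vocab, "pet_vocab"))
  idx <- vocab$index[terms]
  idx[is.na(idx)] <- UNK_INDEX
  unname(idx)
}

#' Map vocabulary indices back to terms
#' @param vocab A `pet_vocab`.
#' @param indices Integer vector of 0-based indices (each `< vocab_size`).
#' @export
vocab_term <- function(vocab, indices) {
  stopifnot(inherits(vocab, "pet_vocab"))
  if (any(indices < 0L | indices >= vocab_size(vocab))) {
    abort("Index out of vocabulary range")
  }
  vocab$terms[indices + 1L]
}

#' @exportS3Method base::print
print.pet_vocab <- function(x, ...) {
  cat(sprintf("<pet_vocab> %d terms (incl. '%s' = 0, '%s' = 1)\n",
              vocab_size(x), PAD_TOKEN, UNK_TOKEN))
  show <- utils::head(x$terms, 8)
  cat("  ", paste(sprintf("%s=%d", show, x$index[show]), collapse = " "),
      if (vocab_size(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
as_tibble.pet_vocab <- function(x, ...) {
  tibble(index = unname(x$index), term = x$terms)
}

#' Write / read a vocabulary as TSV
#'
#' Two columns, `index` and `term`, sorted by index; the reserved entries are
#' written as the literal strings `pad` and `unk`.
#'
#' @param vocab A `pet_vocab`.
#' @param path File path.
#' @return `read_vocab_tsv()` returns a `pet_vocab`;
#'   `write_vocab_tsv()` returns `path` invisibly.
#' @export
write_vocab_tsv <- function(vocab, path) {
  df <- as_tibble(vocab)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_vocab_tsv
#' @export
read_vocab_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character"),
                          quote = "", comment.char = "")
  df <- df[order(df$index), , drop = FALSE]
  if (!identical(df$index, seq_len(nrow(df)) - 1L)) {
    abort("Vocabulary file indices must be contiguous 0..V-1")
  }
  new_pet_vocab(df$term)
}
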