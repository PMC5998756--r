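#' Filter a raw tweet corpus
#'
#' Applies the standard cleaning rules for short-text health corpora before
#' vocabulary building: removes retweets (metadata flag set *or* text starting
#' with the `"RT "` marker), tweets whose language flag is present and not
#' English, tweets containing a URL (metadata flag or an `http(s)://` /
#' `t.co` match in the text), and exact-duplicate texts (first occurrence
#' kept). Sentence punctuation (`. , ! ? ; : " ( )`) is then stripped from the
#' surviving texts; apostrophes are kept so contractions stay intact. Record
#' order is otherwise preserved: the output rows are a subsequence of the
#' input rows.
#'
#' @param tweets A tibble with a `text` column; optional columns `id`,
#'   `label`, `is_retweet`, `lang`, `has_url` are honoured when present.
#'   Records with missing text are skipped with a warning rather than failing
#'   the whole corpus.
#' @return A tibble of surviving tweets with punctuation-stripped `text`.
#' @export
#' @examples
#' tweets <- tibble::tibble(
#'   id = c("a", "b", "c"),
#'   text = c("Thank you aspirin. No more headache",
#'            "RT @x: aspirin works", "see http://t.co/x")
#' )
#' filter_corpus(tweets)
filter_corpus <- function(tweets) {
  check_column(tweets, "text", "tweets")
  tweets <- as_tibble(tweets)
  n0 <- nrow(tweets)

  malformed <- is.na(tweets$text) | !is.character(tweets$text)
  if (any(malformed)) {
    warn(sprintf("Skipping %d malformed record(s) with missing text",
                 sum(malformed)))
    tweets <- tweets[!malformed, , drop = FALSE]
  }

  flag <- function(col) {
    if (col %in% names(tweets)) {
      v <- tweets[[col]]
      !is.na(v) & v
    } else {
      rep(FALSE, nrow(tweets))
    }
  }
  is_rt <- flag("is_retweet") | startsWith(tweets$text, "RT ")
  has_url <- flag("has_url") |
    grepl("https?://|\\bt\\.co/", tweets$text, ignore.case = TRUE)
  # trust the lang field when present; absent/unknown lang is kept
  non_en <- if ("lang" %in% names(tweets)) {
    lang <- tweets$lang
    !is.na(lang) & lang != "" & tolower(lang) != "en"
  } else {
    rep(FALSE, nrow(tweets))
  }

  keep <- !is_rt & !has_url & !non_en
  out <- tweets[keep, , drop = FALSE]
  out <- out[!duplicated(out$text), , drop = FALSE]
  out$text <- strip_punctuation(out$text)
  out
}

# Replace the sentence punctuation set with spaces (token boundaries) and
# collapse runs of whitespace; apostrophes survive inside tokens.
strip_punctuation <- function(text) {
  text <- gsub('[.,!?;:"()]', " ", text)
  trimws(gsub("\\s+", " ", text))
}

#' Tokenize tweet text
#'
#' Splits on whitespace and lowercases. Punctuation is assumed to have been
#' stripped by [filter_corpus()]; the operation is idempotent on its own
#' output and total (empty text yields an empty token vector).
#'
#' @param text A character vector of tweet texts.
#' @return A list of character token vectors, one per input text.
#' @export
#' @examples
#' tokenize("Thank you aspirin No more headache")[[1]]
tokenize <- function(text) {
  text <- tolower(trimws(text))
  out <- strsplit(text, "\\s+")
  map(out, function(tk) tk[nzchar(tk)])
}

#' Tokenize a tweet corpus
#'
#' Tibble-level wrapper around [tokenize()]: returns one row per tweet with a
#' list-column of tokens, carrying the id and (when present) the label.
#'
#' @param tweets A tibble with `text` and optionally `id` and `label` columns.
#' @return A tibble with columns `tweet_id`, `label` (if present in the
#'   input), and list-column `tokens`.
#' @export
tokenize_tweets <- function(tweets) {
  check_column(tweets, "text", "tweets")
  out <- tibble(
    tweet_id = if ("id" %in% names(tweets)) as.character(tweets$id) else
      as.character(seq_len(nrow(tweets))),
    tokens = tokenize(tweets$text)
  )
  if ("label" %in% names(tweets)) {
    out <- add_column(out, label = tweets$label, .after = "tweet_id")
  }
  out
}

# Accept either a tokenized-corpus tibble or a bare list of token vectors.
token_list <- function(sequences) {
  if (is.data.frame(sequences)) {
    check_column(sequences, "tokens", "tokenized corpus")
    sequences$tokens
  } else if (is.list(sequences)) {
    sequences
  } else {
    abort("Expected a tokenized-corpus tibble or a list of token vectors")
  }
}
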