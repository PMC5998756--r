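#' Learn bigram phrases from a tokenized corpus
#'
#' Scores every adjacent token pair with the discounted pointwise-association
#' collocation score
#' \deqn{score(a, b) = \frac{(count(ab) - \delta)\, N}{count(a)\, count(b)}}{
#'   score(a,b) = (count(ab) - delta) * N / (count(a) * count(b))}
#' where \eqn{N} is the total token count of the corpus and \eqn{\delta} a
#' discount that suppresses rare pairs. Pairs scoring above `threshold`
#' become merge rules for [apply_phrases()]. A single pass over bigrams only:
#' longer phrases can be built by re-applying the procedure to merged output.
#'
#' @param sequences A tokenized corpus ([tokenize_tweets()] output) or a bare
#'   list of token vectors.
#' @param discount Non-negative discount \eqn{\delta} (default 5).
#' @param threshold Positive score threshold above which a pair is merged
#'   (default 10).
#' @return A `pet_phrases` object: a tibble of all observed pairs with
#'   columns `token_a`, `token_b`, `n_ab`, `score`, ordered by decreasing
#'   score, with the discount/threshold and corpus token count as attributes.
#' @export
#' @examples
#' seqs <- list(c("side", "effects", "bad"), c("side", "effects"))
#' learn_phrases(seqs, discount = 0, threshold = 1)
learn_phrases <- function(sequences, discount = 5, threshold = 10) {
  seqs <- token_list(sequences)
  stopifnot(discount >= 0, threshold > 0)
  n_tok <- map_int(seqs, length)
  if (length(seqs) == 0 || sum(n_tok) == 0) {
    abort("Cannot learn phrases from an empty corpus: no token statistics")
  }

  all_tokens <- unlist(seqs, use.names = FALSE)
  n_total <- length(all_tokens)
  uni <- table(all_tokens)

  # adjacent pairs within each tweet (never across tweet boundaries)
  keep <- n_tok >= 2
  pairs <- if (any(keep)) {
    a <- unlist(map(seqs[keep], function(tk) tk[-length(tk)]), use.names = FALSE)
    b <- unlist(map(seqs[keep], function(tk) tk[-1]), use.names = FALSE)
    tibble(token_a = a, token_b = b)
  } else {
    tibble(token_a = character(), token_b = character())
  }
  scored <- pairs %>%
    count(.data$token_a, .data$token_b, name = "n_ab") %>%
    mutate(
      score = (.data$n_ab - discount) * n_total /
        (as.numeric(uni[.data$token_a]) * as.numeric(uni[.data$token_b]))
    ) %>%
    arrange(desc(.data$score), .data$token_a, .data$token_b)

  structure(scored,
    class = c("pet_phrases", class(scored)),
    discount = discount, threshold = threshold, n_tokens = n_total
  )
}

#' Merge rules of a phrase model
#'
#' @param phrases A `pet_phrases` object.
#' @return The subset of scored pairs exceeding the model's threshold.
#' @export
phrase_rules <- function(phrases) {
  stopifnot(inherits(phrases, "pet_phrases"))
  phrases[phrases$score > attr(phrases, "threshold"), , drop = FALSE]
}

#' Apply learned phrase merges to token sequences
#'
#' Greedy left-to-right merge of adjacent pairs that are rules of the phrase
#' model; a merged pair becomes a single token joined by `"_"`. Merges do not
#' overlap: after a merge, scanning resumes *after* the merged pair, so in
#' `(a, b, c)` with rules `{(a,b), (b,c)}` only `a_b` is formed. Token count
#' never increases.
#'
#' @param phrases A `pet_phrases` object (or anything [phrase_rules()]
#'   accepts).
#' @param sequences A tokenized corpus tibble, a bare list of token vectors,
#'   or a single character vector of tokens.
#' @return Same shape as `sequences`, with merges applied.
#' @export
apply_phrases <- function(phrases, sequences) {
  rules <- phrase_rules(phrases)
  rule_keys <- paste(rules$token_a, rules$token_b, sep = "\r")

  merge_one <- function(tk) {
    n <- length(tk)
    if (n < 2 || length(rule_keys) == 0) return(tk)
    out <- character(0)
    i <- 1L
    while (i <= n) {
      if (i < n && paste(tk[i], tk[i + 1L], sep = "\r") %in% rule_keys) {
        out <- c(out, paste(tk[i], tk[i + 1L], sep = "_"))
        i <- i + 2L
      } else {
        out <- c(out, tk[i])
        i <- i + 1L
      }
    }
    out
  }

  if (is.character(sequences)) return(merge_one(sequences))
  if (is.data.frame(sequences)) {
    sequences$tokens <- map(sequences$tokens, merge_one)
    return(sequences)
  }
  map(sequences, merge_one)
}

#' @exportS3Method base::print
print.pet_phrases <- function(x, ...) {
  n_rules <- sum(x$score > attr(x, "threshold"))
  cat(sprintf(
    "<pet_phrases> %d scored pair(s), %d merge rule(s) (discount %.3g, threshold %.3g)\n",
    nrow(x), n_rules, attr(x, "discount"), attr(x, "threshold")
  ))
  NextMethod()
}
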