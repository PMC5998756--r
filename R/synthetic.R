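#' Specify a synthetic tweet corpus
#'
#' Builds a validated specification for the synthetic corpus generators
#' ([synth_labeled_corpus()] and [synth_unlabeled_corpus()]). The generators
#' emulate the two corpora the classification pipeline consumes: a large
#' unlabeled corpus with plantable token co-occurrence structure (for
#' embedding training and filter testing) and a labeled, class-imbalanced
#' corpus whose PET / non-PET classes differ in token distribution and,
#' optionally, in token order.
#'
#' The token model: each tweet draws its length from a Poisson distribution
#' (mean `mean_length`) truncated to `[1, max_length]`. Each token position is
#' a "signal" position with probability `signal_rate`; a signal token is drawn
#' from the tweet's own-class indicator set with odds `signal_odds` to 1
#' against the opposite-class set. Non-signal positions draw from a shared
#' Zipf-weighted background vocabulary, so with `signal_odds = 1` the two
#' classes are identically distributed. With `order_sensitive = TRUE` every
#' tweet additionally contains one first-person token and one symptom token —
#' at the same marginal rate in both classes — whose *relative order* encodes
#' the class (first-person before symptom for PET, the reverse for non-PET).
#' An order-free bag-of-words representation is blind to that component of
#' the signal while a sequence model is not.
#'
#' @param n_tweets Number of tweets to generate.
#' @param pet_fraction Probability that a tweet is a PET (positive class).
#' @param vocab_size Number of background token types.
#' @param mean_length Mean of the (truncated) Poisson tweet length.
#' @param max_length Maximum tweet length in tokens (at most 48 by default
#'   downstream; lengths are truncated here, not downstream).
#' @param signal_odds Relative over-representation of own-class signal tokens
#'   (`>= 1`; `1` means no distributional class signal).
#' @param signal_rate Probability that a token position carries a class
#'   signal token rather than a background token.
#' @param order_sensitive If `TRUE`, class membership additionally depends on
#'   the order of a first-person / symptom token pair (see Details).
#' @param noise_rate Probability of flipping each label after generation.
#' @param exact_counts If `TRUE`, exactly `round(n_tweets * pet_fraction)`
#'   tweets are PET (positions shuffled); otherwise labels are i.i.d.
#'   Bernoulli.
#' @param retweet_fraction,url_fraction,duplicate_fraction,nonenglish_fraction
#'   Fractions of records corrupted for filter testing: prefixed with the
#'   retweet marker, given an embedded URL, replaced by an exact duplicate of
#'   an earlier tweet, or flagged as non-English. Only used by
#'   [synth_unlabeled_corpus()].
#' @param planted_pair Character vector of two tokens that, when planted,
#'   always appear adjacent (perfect co-occurrence); used to test embedding
#'   geometry. `NULL` to disable.
#' @param lone_token A token that never co-occurs with `planted_pair[1]`.
#' @param planted_rate Probability that a tweet carries the planted pair (and,
#'   independently among the remaining tweets, the lone token).
#' @param seed Integer seed; generation is fully reproducible.
#'
#' @return An object of class `pet_corpus_spec` (a named list).
#' @export
#' @examples
#' spec <- synth_corpus_spec(n_tweets = 100, seed = 42)
#' tweets <- synth_labeled_corpus(spec)
#' dplyr::count(tweets, label)
synth_corpus_spec <- function(n_tweets = 2000,
                              pet_fraction = 0.25,
                              vocab_size = 500,
                              mean_length = 12,
                              max_length = 48,
                              signal_odds = 4,
                              signal_rate = 0.3,
                              order_sensitive = FALSE,
                              noise_rate = 0,
                              exact_counts = FALSE,
                              retweet_fraction = 0,
                              url_fraction = 0,
                              duplicate_fraction = 0,
                              nonenglish_fraction = 0,
                              planted_pair = NULL,
                              lone_token = NULL,
                              planted_rate = 0,
                              seed = 1L) {
  check_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi ||
        (integer && x != round(x))) {
      abort(sprintf("Invalid corpus spec field '%s'", name))
    }
  }
  check_scalar(n_tweets, "n_tweets", lo = 1, integer = TRUE)
  check_scalar(pet_fraction, "pet_fraction", lo = 1e-9, hi = 1 - 1e-9)
  check_scalar(vocab_size, "vocab_size", lo = 2, integer = TRUE)
  check_scalar(mean_length, "mean_length", lo = 1e-9)
  check_scalar(max_length, "max_length", lo = 1, integer = TRUE)
  check_scalar(signal_odds, "signal_odds", lo = 1)
  check_scalar(signal_rate, "signal_rate", lo = 0, hi = 1)
  check_scalar(noise_rate, "noise_rate", lo = 0, hi = 1 - 1e-9)
  check_scalar(seed, "seed", integer = TRUE)
  for (f in c("retweet_fraction", "url_fraction", "duplicate_fraction",
              "nonenglish_fraction", "planted_rate")) {
    check_scalar(get(f), f, lo = 0, hi = 1)
  }
  if (!is.logical(order_sensitive) || length(order_sensitive) != 1) {
    abort("Invalid corpus spec field 'order_sensitive'")
  }
  if (!is.null(planted_pair) &&
      (!is.character(planted_pair) || length(planted_pair) != 2)) {
    abort("Invalid corpus spec field 'planted_pair'")
  }

  lex <- synth_lexicon(vocab_size)
  structure(
    list(
      n_tweets = as.integer(n_tweets), pet_fraction = pet_fraction,
      vocab_size = as.integer(vocab_size), mean_length = mean_length,
      max_length = as.integer(max_length), signal_odds = signal_odds,
      signal_rate = signal_rate, order_sensitive = isTRUE(order_sensitive),
      noise_rate = noise_rate, exact_counts = isTRUE(exact_counts),
      retweet_fraction = retweet_fraction, url_fraction = url_fraction,
      duplicate_fraction = duplicate_fraction,
      nonenglish_fraction = nonenglish_fraction,
      planted_pair = planted_pair, lone_token = lone_token,
      planted_rate = planted_rate,
      seed = as.integer(seed), lexicon = lex
    ),
    class = "pet_corpus_spec"
  )
}

# Token alphabet: a small English-like lexicon so generated examples read like
# real health tweets, padded with synthetic "tokNNNN" types under Zipf weights.
# The PET / non-PET indicator sets and the order-encoding sets are mutually
# disjoint and disjoint from the background.
synth_lexicon <- function(vocab_size) {
  signal_pet <- c("took", "feel", "felt", "helped", "relief", "finally")
  signal_nonpet <- c("news", "study", "fda", "report", "sale", "offer")
  first_person <- c("i", "my", "me")
  symptom <- c("headache", "migraine", "nausea")
  drugs <- c("aspirin", "ibuprofen", "tylenol", "benadryl", "zyrtec")
  n_extra <- max(0L, vocab_size - length(drugs))
  background <- c(drugs, sprintf("tok%04d", seq_len(n_extra)))
  background <- utils::head(background, vocab_size)
  list(
    signal_pet = signal_pet, signal_nonpet = signal_nonpet,
    first_person = first_person, symptom = symptom,
    background = background,
    background_prob = local({
      w <- 1 / seq_along(background)  # Zipf weights
      w / sum(w)
    })
  )
}

#' Generate a labeled synthetic tweet corpus
#'
#' Draws a corpus of PET / non-PET tweets from the token model described in
#' [synth_corpus_spec()]. Reproducible: the same spec (including its seed)
#' yields a byte-identical corpus.
#'
#' @param spec A `pet_corpus_spec`.
#' @return A tibble with columns `id`, `text`, `label` (`"PET"` /
#'   `"nonPET"`), `is_retweet`, `lang`, `has_url`.
#' @export
synth_labeled_corpus <- function(spec) {
  stopifnot(inherits(spec, "pet_corpus_spec"))
  with_seed(spec$seed, synth_generate(spec, labeled = TRUE))
}

#' Generate an unlabeled synthetic tweet corpus
#'
#' Same token model as [synth_labeled_corpus()] (class membership is drawn but
#' not reported), plus optional planted always-co-occurring token pairs for
#' embedding tests and configurable fractions of retweet / URL / duplicate /
#' non-English records for filter tests.
#'
#' @inheritParams synth_labeled_corpus
#' @return A tibble with columns `id`, `text`, `label` (all `NA`),
#'   `is_retweet`, `lang`, `has_url`.
#' @export
synth_unlabeled_corpus <- function(spec) {
  stopifnot(inherits(spec, "pet_corpus_spec"))
  with_seed(spec$seed + 1L, synth_generate(spec, labeled = FALSE))
}

synth_generate <- function(spec, labeled) {
  n <- spec$n_tweets
  lex <- spec$lexicon

  if (spec$exact_counts) {
    n_pet <- round(n * spec$pet_fraction)
    y <- sample(rep(c(1L, 0L), c(n_pet, n - n_pet)))
  } else {
    y <- rbinom(n, 1L, spec$pet_fraction)
  }

  # truncated Poisson lengths in [1, max_length]
  len <- rpois(n, spec$mean_length)
  len <- pmin(pmax(len, 1L), spec$max_length)
  q_own <- spec$signal_odds / (spec$signal_odds + 1)

  tokens <- vector("list", n)
  for (i in seq_len(n)) {
    L <- len[i]
    is_sig <- runif(L) < spec$signal_rate
    tk <- character(L)
    n_bg <- sum(!is_sig)
    if (n_bg > 0) {
      tk[!is_sig] <- sample(lex$background, n_bg, replace = TRUE,
                            prob = lex$background_prob)
    }
    n_sig <- sum(is_sig)
    if (n_sig > 0) {
      own <- runif(n_sig) < q_own
      own_set <- if (y[i] == 1L) lex$signal_pet else lex$signal_nonpet
      other_set <- if (y[i] == 1L) lex$signal_nonpet else lex$signal_pet
      sig_tk <- character(n_sig)
      if (any(own)) sig_tk[own] <- sample(own_set, sum(own), replace = TRUE)
      if (any(!own)) sig_tk[!own] <- sample(other_set, sum(!own), replace = TRUE)
      tk[is_sig] <- sig_tk
    }
    if (spec$order_sensitive) {
      # one first-person and one symptom token at the same rate in both
      # classes; their order is the class-defining feature.
      if (length(tk) < 2) tk <- c(tk, sample(lex$background, 1))
      pos <- sort(sample(length(tk), 2))
      fp <- sample(lex$first_person, 1)
      sym <- sample(lex$symptom, 1)
      if (y[i] == 1L) {
        tk[pos[1]] <- fp; tk[pos[2]] <- sym
      } else {
        tk[pos[1]] <- sym; tk[pos[2]] <- fp
      }
    }
    tokens[[i]] <- tk
  }

  if (spec$noise_rate > 0) {
    flip <- runif(n) < spec$noise_rate
    y[flip] <- 1L - y[flip]
  }

  out <- tibble(
    id = sprintf("t%06d", seq_len(n)),
    text = map_chr(tokens, paste, collapse = " "),
    label = if (labeled) binary_to_label(y) else NA_character_,
    is_retweet = FALSE,
    lang = "en",
    has_url = FALSE
  )
  if (!labeled) out <- synth_corrupt(out, spec)
  out
}

# Plant co-occurrence structure and corrupt records for filter tests.
synth_corrupt <- function(out, spec) {
  n <- nrow(out)

  if (!is.null(spec$planted_pair) && spec$planted_rate > 0) {
    # Planted tweets are topical, as real co-occurrence structure is: tweets
    # carrying the pair draw their background from one half of the
    # vocabulary, tweets carrying the lone token from the other half. The
    # pair is inserted adjacently, so the two tokens always co-occur within
    # any window; the lone token never shares a tweet with the pair.
    bg <- spec$lexicon$background
    half <- max(1L, length(bg) %/% 2L)
    topic_a <- bg[seq_len(half)]
    topic_b <- bg[(half + 1L):length(bg)]
    rebuild <- function(topic, planted) {
      L <- max(2L, min(rpois(1, spec$mean_length), spec$max_length))
      tk <- sample(topic, L, replace = TRUE)
      pos <- sample(L - 1L, 1L)
      paste(append(tk, planted, after = pos), collapse = " ")
    }
    carry <- runif(n) < spec$planted_rate
    lone <- !carry & runif(n) < spec$planted_rate
    for (i in which(carry)) out$text[i] <- rebuild(topic_a, spec$planted_pair)
    if (!is.null(spec$lone_token)) {
      for (i in which(lone)) out$text[i] <- rebuild(topic_b, spec$lone_token)
    }
  }

  mark_first <- function(frac) {
    k <- floor(frac * n)
    if (k == 0) return(integer(0))
    sample(n, k)
  }
  rt_idx <- mark_first(spec$retweet_fraction)
  if (length(rt_idx)) {
    out$text[rt_idx] <- paste0("RT @user: ", out$text[rt_idx])
    # half flagged in metadata, half detectable only through the text prefix
    flagged <- rt_idx[seq_along(rt_idx) %% 2 == 1]
    out$is_retweet[flagged] <- TRUE
  }
  url_idx <- mark_first(spec$url_fraction)
  if (length(url_idx)) {
    out$text[url_idx] <- paste0(out$text[url_idx], " http://t.co/",
                                substr(out$id[url_idx], 2, 7))
    out$has_url[url_idx] <- TRUE
  }
  lang_idx <- mark_first(spec$nonenglish_fraction)
  if (length(lang_idx)) out$lang[lang_idx] <- "es"
  dup_k <- floor(spec$duplicate_fraction * n)
  if (dup_k > 0 && n > dup_k) {
    src <- sample(n - dup_k, dup_k, replace = TRUE)
    tgt <- (n - dup_k + 1):n
    out$text[tgt] <- out$text[src]
  }
  out
}

#' @exportS3Method base::print
print.pet_corpus_spec <- function(x, ...) {
  cat("<pet_corpus_spec>\n")
  cat(sprintf("  n_tweets: %d  pet_fraction: %.3f  seed: %d\n",
              x$n_tweets, x$pet_fraction, x$seed))
  cat(sprintf("  signal_odds: %.2f  signal_rate: %.2f  order_sensitive: %s\n",
              x$signal_odds, x$signal_rate, x$order_sensitive))
  cat(sprintf("  vocab_size: %d  mean_length: %.1f  max_length: %d\n",
              x$vocab_size, x$mean_length, x$max_length))
  invisible(x)
}
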