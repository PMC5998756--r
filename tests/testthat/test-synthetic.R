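test_that("labeled generation honours counts, reproducibility and validation", {
  spec <- synth_corpus_spec(n_tweets = 1000, pet_fraction = 0.25, seed = 7)
  tw <- synth_labeled_corpus(spec)
  expect_equal(nrow(tw), 1000)
  expect_true(all(tw$label %in% c("PET", "nonPET")))
  # binomial label count: within 4 sd of the mean
  expect_lt(abs(sum(tw$label == "PET") - 250), 4 * sqrt(1000 * 0.25 * 0.75))

  exact <- synth_labeled_corpus(
    synth_corpus_spec(n_tweets = 1000, pet_fraction = 0.25,
                      exact_counts = TRUE, seed = 7)
  )
  expect_equal(sum(exact$label == "PET"), 250)

  # byte-identical under the same seed
  expect_identical(synth_labeled_corpus(spec), tw)
  expect_false(identical(
    synth_labeled_corpus(synth_corpus_spec(n_tweets = 1000, seed = 8)), tw
  ))

  expect_error(synth_corpus_spec(pet_fraction = 2), "pet_fraction")
  expect_error(synth_corpus_spec(signal_odds = 0.5), "signal_odds")
  expect_error(synth_corpus_spec(n_tweets = 0), "n_tweets")
})

test_that("tweet lengths stay within [1, max_length]", {
  tw <- synth_labeled_corpus(
    synth_corpus_spec(n_tweets = 500, mean_length = 20, max_length = 24,
                      seed = 1)
  )
  lens <- lengths(tokenize(tw$text))
  expect_gte(min(lens), 1)
  expect_lte(max(lens), 24)
})

test_that("signal_odds = 1 without order sensitivity yields exchangeable classes", {
  # the two classes then share one token distribution: a BoW classifier's
  # held-out AUC should hover at chance
  tw <- synth_labeled_corpus(
    synth_corpus_spec(n_tweets = 1200, signal_odds = 1, seed = 3)
  )
  tok <- tokenize_tweets(tw)
  half <- 600
  bow_tr <- bow_vectorize(tok[1:half, ])
  fit <- fit_logreg(bow_tr, tw$label[1:half], C = 1)
  pred <- predict(fit, bow_project(tok[(half + 1):1200, ], fit$terms))
  auc <- roc_auc(tw$label[(half + 1):1200], pred$probability)
  expect_lt(abs(auc - 0.5), 0.08)
})

test_that("order-sensitive corpora encode class in token order", {
  tw <- synth_labeled_corpus(
    synth_corpus_spec(n_tweets = 300, order_sensitive = TRUE, seed = 5)
  )
  lex <- synth_corpus_spec(seed = 1)$lexicon
  ok <- vapply(seq_len(nrow(tw)), function(i) {
    tk <- tokenize(tw$text[i])[[1]]
    fp <- which(tk %in% lex$first_person)
    sym <- which(tk %in% lex$symptom)
    if (length(fp) == 0 || length(sym) == 0) return(FALSE)
    if (tw$label[i] == "PET") min(fp) < min(sym) else min(sym) < min(fp)
  }, TRUE)
  expect_true(all(ok))
})

test_that("planted pairs always co-occur and the lone token avoids them", {
  tw <- synth_unlabeled_corpus(synth_corpus_spec(
    n_tweets = 500, planted_pair = c("xx", "yy"), lone_token = "zz",
    planted_rate = 0.3, seed = 2
  ))
  has <- function(tok) grepl(paste0("\\b", tok, "\\b"), tw$text)
  expect_true(all(has("yy")[has("xx")]))
  expect_false(any(has("zz") & has("xx")))
  expect_gt(sum(has("xx")), 0)
  expect_gt(sum(has("zz")), 0)
})

test_that("corruption fractions feed the corpus filter as designed", {
  n <- 1000
  tw <- synth_unlabeled_corpus(synth_corpus_spec(
    n_tweets = n, retweet_fraction = 0.2, url_fraction = 0.1,
    duplicate_fraction = 0.1, nonenglish_fraction = 0.05, seed = 4
  ))
  expect_gte(sum(duplicated(tw$text)), 0.1 * n * 0.5)
  kept <- suppressWarnings(filter_corpus(tw))
  # at least the retweet records are gone (marker or flag), plus URLs etc.
  expect_lte(nrow(kept), n - 0.2 * n)
  expect_false(any(startsWith(kept$text, "RT ")))
  expect_false(any(grepl("t\\.co/", kept$text)))
  expect_false(any(kept$lang != "en", na.rm = TRUE))
  expect_false(any(duplicated(kept$text)))
})

test_that("generated corpora run the full pipeline end to end", {
  spec <- synth_corpus_spec(n_tweets = 150, seed = 10)
  tw <- synth_labeled_corpus(spec)
  unl <- synth_unlabeled_corpus(spec)
  pipe <- pet_pipeline(tw, unlabeled = unl, dim = 8, hidden_size = 8,
                       embed_epochs = 2, epochs = 1, seed = 1)
  pr <- predict(pipe, tw)
  expect_equal(nrow(pr), nrow(tw))
  expect_true(all(pr$probability > 0 & pr$probability < 1))
  expect_true(all(pr$label %in% c("PET", "nonPET")))
})

test_that("tweet JSON-lines and TSV readers round-trip and tolerate damage", {
  tw <- synth_labeled_corpus(synth_corpus_spec(n_tweets = 20, seed = 6))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tweets_jsonl(tw, path)
  back <- read_tweets_jsonl(path)
  expect_equal(back$text, tw$text)
  expect_equal(back$label, tw$label)

  writeLines(c(readLines(path), "{not json"), path)
  expect_warning(damaged <- read_tweets_jsonl(path), "malformed")
  expect_equal(nrow(damaged), 20)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("PET\ttook aspirin relief", "nonPET\tfda news report"), tsv)
  tt <- read_tweets_tsv(tsv)
  expect_equal(tt$label, c("PET", "nonPET"))
  expect_equal(tt$text[2], "fda news report")
})
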