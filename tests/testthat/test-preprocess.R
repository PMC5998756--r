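test_that("filter_corpus removes retweets, URLs, non-English and duplicates", {
  tweets <- tibble::tibble(
    id = as.character(1:8),
    text = c(
      "Thank you aspirin. No more headache",   # survives, punctuation stripped
      "RT @a: aspirin works",                  # retweet by text marker
      "flagged retweet",                       # retweet by metadata
      "check this http://t.co/x",              # URL in text
      "url by metadata",                       # URL by metadata
      "hola que tal",                          # non-English by lang field
      "Thank you aspirin. No more headache",   # exact duplicate of 1
      "took tylenol today"                     # survives
    ),
    is_retweet = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    lang = c("en", "en", "en", "en", "en", "es", "en", NA),
    has_url = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  out <- filter_corpus(tweets)
  expect_equal(out$id, c("1", "8"))
  expect_equal(out$text[1], "Thank you aspirin No more headache")
  # output ids are a subsequence of input ids
  expect_true(all(diff(match(out$id, tweets$id)) > 0))
})

test_that("filter_corpus skips malformed records with a warning", {
  tweets <- tibble::tibble(id = c("a", "b"), text = c(NA, "fine"))
  expect_warning(out <- filter_corpus(tweets), "malformed")
  expect_equal(out$id, "b")
})

test_that("punctuation stripping keeps apostrophes and strips the listed set", {
  expect_equal(petminer:::strip_punctuation('don\'t stop! (really): "ok"; yes?'),
               "don't stop really ok yes")
})

test_that("tokenize lowercases, splits on whitespace, and is total", {
  tk <- tokenize("Thank you aspirin No more headache")[[1]]
  expect_equal(tk, c("thank", "you", "aspirin", "no", "more", "headache"))
  expect_length(tk, 6)
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize("aspirin   aspirin")[[1]], c("aspirin", "aspirin"))
})

test_that("tokenization is idempotent under rejoin", {
  texts <- c("a b  c", "  x y ", "one")
  once <- tokenize(texts)
  rejoined <- vapply(once, paste, "", collapse = " ")
  expect_equal(tokenize(rejoined), once)
})

test_that("tokenize_tweets carries ids and labels", {
  tw <- tibble::tibble(id = c("t1", "t2"), text = c("a b", "c"),
                       label = c("PET", "nonPET"))
  tok <- tokenize_tweets(tw)
  expect_equal(tok$tweet_id, c("t1", "t2"))
  expect_equal(tok$label, c("PET", "nonPET"))
  expect_equal(tok$tokens[[2]], "c")
})

test_that("phrase scores match the worked collocation example", {
  # 10 copies of (side, effects) plus 10 distinct unrelated tokens:
  # N = 30, count(side) = count(effects) = count(side effects) = 10
  # => score = (10 - 0) * 30 / (10 * 10) = 3.0
  seqs <- c(replicate(10, c("side", "effects"), simplify = FALSE),
            as.list(sprintf("u%02d", 1:10)))
  ph <- learn_phrases(seqs, discount = 0, threshold = 2)
  row <- dplyr::filter(ph, token_a == "side", token_b == "effects")
  expect_equal(row$score, 3.0)
  expect_equal(nrow(phrase_rules(ph)), 1)
})

test_that("phrase scores equal brute-force counts on random toy corpora", {
  set.seed(42)
  for (rep in 1:5) {
    seqs <- replicate(30, sample(letters[1:6], sample(1:12, 1), replace = TRUE),
                      simplify = FALSE)
    stopifnot(sum(lengths(seqs)) <= 1000)
    for (disc in c(0, 1, 5)) {
      got <- learn_phrases(seqs, discount = disc, threshold = 1)
      want <- brute_force_phrase_scores(seqs, disc)
      merged <- dplyr::inner_join(
        as.data.frame(got), want, by = c("token_a", "token_b")
      )
      expect_equal(nrow(merged), nrow(got))
      expect_equal(nrow(got), nrow(want))
      expect_equal(merged$score.x, merged$score.y, tolerance = 1e-12)
    }
  }
})

test_that("phrase edge cases: high threshold, forced-zero score, empty corpus", {
  seqs <- list(c("a", "b"), c("c", "d"))
  expect_equal(nrow(phrase_rules(learn_phrases(seqs, threshold = 1e9))), 0)
  # pair occurring once with discount 1 -> numerator zero -> never merged
  ph <- learn_phrases(list(c("x", "y")), discount = 1, threshold = 0.5)
  expect_equal(ph$score[ph$token_a == "x"], 0)
  expect_error(learn_phrases(list()), "empty")
})

test_that("apply_phrases merges greedily left-to-right without overlap", {
  # single rule (side, effects)
  one_rule <- structure(
    tibble::tibble(token_a = "side", token_b = "effects",
                   n_ab = 10L, score = 3),
    class = c("pet_phrases", class(tibble::tibble())),
    discount = 0, threshold = 2, n_tokens = 30
  )
  expect_equal(apply_phrases(one_rule, c("bad", "side", "effects")),
               c("bad", "side_effects"))

  # a learned model merges its high-scoring pair the same way
  ph <- learn_phrases(
    c(replicate(10, c("side", "effects"), simplify = FALSE),
      as.list(sprintf("u%02d", 1:10)), list(c("bad", "pain"))),
    discount = 0, threshold = 2
  )
  expect_equal(apply_phrases(ph, c("bad", "side", "effects")),
               c("bad", "side_effects"))

  # rules {(a,b),(b,c)} on (a,b,c): greedy left-to-right gives (a_b, c)
  fake <- structure(
    tibble::tibble(token_a = c("a", "b"), token_b = c("b", "c"),
                   n_ab = c(5L, 5L), score = c(9, 9)),
    class = c("pet_phrases", class(tibble::tibble())),
    discount = 0, threshold = 1, n_tokens = 10
  )
  expect_equal(apply_phrases(fake, c("a", "b", "c")), c("a_b", "c"))

  # empty rule set is the identity; token count never increases
  none <- learn_phrases(list(c("q", "r")), threshold = 1e9)
  expect_equal(apply_phrases(none, c("q", "r", "q")), c("q", "r", "q"))
  set.seed(7)
  for (i in 1:20) {
    tk <- sample(c("a", "b", "c", "d"), sample(1:10, 1), replace = TRUE)
    expect_lte(length(apply_phrases(fake, tk)), length(tk))
  }
})
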