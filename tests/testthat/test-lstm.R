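test_that("class weights reproduce the majority/minority ratio rule", {
  w <- compute_class_weights(2650, 6547)
  expect_equal(w$w_pos, 6547 / 2650, tolerance = 1e-12)
  expect_equal(w$w_neg, 2650 / 6547, tolerance = 1e-12)
  expect_equal(w$w_pos, 2.4706, tolerance = 1e-4)
  expect_equal(w$w_neg, 0.4048, tolerance = 1e-4)

  wb <- compute_class_weights(100, 100)
  expect_equal(c(wb$w_pos, wb$w_neg), c(1, 1))
  expect_error(compute_class_weights(0, 10), "positive")
  expect_error(compute_class_weights(10, 0), "positive")
})

test_that("degenerate parameter settings force closed-form outputs", {
  v <- make_vocab(c("a", "b"))
  p <- lstm_params(make_embedding(v, 2), hidden_size = 3, init = "zero")
  # everything zero: all gates 0.5, candidate 0, cell stays 0 -> p = sigma(0)
  expect_equal(lstm_forward(p, c(2L, 3L, 0L)), 0.5)
  p$b_out <- 10
  expect_equal(lstm_forward(p, c(2L, 3L, 0L)), stats::plogis(10),
               tolerance = 1e-12)
  expect_equal(lstm_forward(p, c(3L, 0L, 0L)), stats::plogis(10),
               tolerance = 1e-12)
})

test_that("forward pass matches the hand-unrolled recurrence oracle", {
  v <- make_vocab(c("a", "b"))
  p <- toy_params(v, d = 2, h = 2)
  # 2-step toy, then longer padded sequences
  for (idx in list(c(2L, 3L), c(3L, 2L, 0L, 0L), c(2L, 2L, 3L, 2L, 0L))) {
    expect_equal(lstm_forward(p, idx), unrolled_lstm_prob(p, idx),
                 tolerance = 1e-10)
  }
  # batched forward agrees with per-sequence forward
  X <- rbind(c(2L, 3L, 0L), c(3L, 3L, 2L))
  expect_equal(lstm_forward(p, X),
               c(unrolled_lstm_prob(p, X[1, ]), unrolled_lstm_prob(p, X[2, ])),
               tolerance = 1e-10)
})

test_that("weighted loss matches closed forms and reduces when unweighted", {
  w1 <- compute_class_weights(1, 1)
  expect_equal(weighted_loss(0.5, 1, w1), log(2), tolerance = 1e-12)
  w2 <- structure(list(w_pos = 2, w_neg = 1), class = "pet_class_weights")
  expect_equal(weighted_loss(0.5, 1, w2), 2 * log(2), tolerance = 1e-12)
  # unit weights reduce to plain cross-entropy for arbitrary (p, y)
  set.seed(1)
  p <- runif(20, 0.01, 0.99); y <- rbinom(20, 1, 0.5)
  expect_equal(weighted_loss(p, y, w1),
               mean(-(y * log(p) + (1 - y) * log(1 - p))), tolerance = 1e-12)
  # p = 0 and 1 are clipped, not infinite
  expect_true(is.finite(weighted_loss(c(0, 1), c(1, 0), w1)))
})

test_that("increasing the positive weight increases a misclassified positive's loss", {
  p <- 0.2; y <- 1  # misclassified positive
  losses <- vapply(c(1, 2, 4, 8), function(wp) {
    weighted_loss(p, y, structure(list(w_pos = wp, w_neg = 1),
                                  class = "pet_class_weights"))
  }, 0)
  expect_true(all(diff(losses) > 0))
})

test_that("analytic gradients match central finite differences", {
  v <- make_vocab(c("a", "b", "c"))
  p <- toy_params(v, d = 4, h = 4, seed = 8)
  set.seed(9)
  X <- matrix(sample(0:4, 3 * 6, replace = TRUE), nrow = 3)  # 3 examples, T=6
  y <- c(1, 0, 1)
  w <- compute_class_weights(2, 1)
  lambda <- 0.01
  tl <- rowSums(X != 0)

  loss_at <- function(par) {
    fp <- lstm_forward(par, X)
    weighted_loss(fp, y, w, par, lambda)
  }
  gr <- petminer:::lstm_loss_grads(p, X, y, w, lambda, true_length = tl,
                                   masked = FALSE)
  expect_equal(gr$loss, loss_at(p), tolerance = 1e-12)

  step <- 1e-5
  for (gname in c("W", "U", "b", "w_out", "b_out", "E")) {
    fd <- p[[gname]]
    fd[] <- NA_real_
    for (j in seq_along(p[[gname]])) {
      pp <- p; pp[[gname]][j] <- pp[[gname]][j] + step
      pm <- p; pm[[gname]][j] <- pm[[gname]][j] - step
      fd[j] <- (loss_at(pp) - loss_at(pm)) / (2 * step)
    }
    if (gname == "E") fd[1, ] <- 0  # pad row is frozen by contract
    an <- gr$grads[[gname]]
    rel <- sqrt(sum((an - fd)^2)) / (sqrt(sum(fd^2)) + sqrt(sum(an^2)) + 1e-12)
    expect_lt(rel, 1e-4)
  }
})

test_that("padding is neutral under masked readout", {
  v <- make_vocab(c("a", "b"))
  p <- toy_params(v, d = 2, h = 2, seed = 5)
  short <- c(2L, 3L, 0L, 0L)
  long <- c(2L, 3L, rep(0L, 8))
  expect_equal(lstm_forward(p, short, true_length = 2L, masked = TRUE),
               lstm_forward(p, long, true_length = 2L, masked = TRUE),
               tolerance = 1e-12)
  # unmasked readout sees the zero-vector recurrence, so may differ
  expect_equal(lstm_forward(p, matrix(short, 1))[1],
               unrolled_lstm_prob(p, short), tolerance = 1e-10)
})

test_that("training on a separable signal corpus reaches high training accuracy", {
  # statistical oracle: majority over 3 seeds
  hits <- 0
  for (s in 1:3) {
    # strongly separable: most tokens carry class signal at high odds
    tw <- make_signal_corpus(n = 500, seed = s, odds = 20, rate = 0.6)
    tok <- tokenize_tweets(tw)
    v <- build_vocabulary(tok)
    emb <- train_embeddings(tok, v, dim = 64, epochs = 50, seed = s)
    enc <- encode_corpus(tok, v, max_len = 24)
    m <- fit_pet_lstm(enc, emb, hidden_size = 64, epochs = 5, seed = s)
    pr <- predict(m, enc)
    acc <- mean(pr$label == tw$label)
    hits <- hits + (acc >= 0.95)
  }
  expect_gte(hits, 2)
})

test_that("training is deterministic and rejects invalid configurations", {
  tw <- make_signal_corpus(n = 80, seed = 4)
  tok <- tokenize_tweets(tw)
  v <- build_vocabulary(tok)
  emb <- train_embeddings(tok, v, dim = 8, epochs = 2, seed = 1)
  enc <- encode_corpus(tok, v, max_len = 12)

  m1 <- fit_pet_lstm(enc, emb, hidden_size = 8, epochs = 2, seed = 3)
  m2 <- fit_pet_lstm(enc, emb, hidden_size = 8, epochs = 2, seed = 3)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$W, m2$params$W)

  expect_error(fit_pet_lstm(enc, emb, epochs = 0), "epochs")
  one_class <- enc
  one_class$label <- rep("PET", nrow(one_class))
  expect_error(fit_pet_lstm(one_class, emb, epochs = 1), "both classes")
})

test_that("prediction thresholds behave at the boundaries", {
  v <- make_vocab(c("a", "b"))
  emb <- make_embedding(v, 2)
  p <- lstm_params(emb, hidden_size = 2, init = "zero")
  model <- structure(
    list(params = p,
         config = list(threshold = 0.5, masked_readout = FALSE),
         vocab = v),
    class = "pet_lstm"
  )
  tok <- tibble::tibble(tweet_id = c("x", "y"),
                        tokens = list("a", c("b", "b")))
  enc <- encode_corpus(tok, v, max_len = 3)
  # zero parameters: p = 0.5 everywhere; >= rule labels PET at 0.5
  pr <- predict(model, enc)
  expect_equal(pr$probability, c(0.5, 0.5))
  expect_equal(pr$label, c("PET", "PET"))
  expect_equal(predict(model, enc, threshold = 0)$label, c("PET", "PET"))
  expect_equal(predict(model, enc, threshold = 1)$label, c("nonPET", "nonPET"))
})

test_that("model checkpoints round-trip through the JSON archive", {
  tw <- make_signal_corpus(n = 60, seed = 6)
  tok <- tokenize_tweets(tw)
  v <- build_vocabulary(tok)
  emb <- train_embeddings(tok, v, dim = 6, epochs = 1, seed = 1)
  enc <- encode_corpus(tok, v, max_len = 10)
  m <- fit_pet_lstm(enc, emb, hidden_size = 6, epochs = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_pet_lstm(m, path)
  back <- read_pet_lstm(path)
  expect_equal(back$params$W, m$params$W, tolerance = 1e-12)
  expect_equal(predict(back, enc)$probability, predict(m, enc)$probability,
               tolerance = 1e-12)
  expect_equal(back$vocab$terms, v$terms)
})
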