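# Independent single-example LSTM oracle: per-gate matrices, scalar recurrence
# unrolled step by step, no shared code with the implementation.
unrolled_lstm_prob <- function(params, idx0) {
  h <- params$h
  blk <- function(M, k) M[, ((k - 1) * h + 1):(k * h), drop = FALSE]
  Wi <- blk(params$W, 1); Wf <- blk(params$W, 2)
  Wg <- blk(params$W, 3); Wo <- blk(params$W, 4)
  Ui <- blk(params$U, 1); Uf <- blk(params$U, 2)
  Ug <- blk(params$U, 3); Uo <- blk(params$U, 4)
  bi <- params$b[1:h]; bf <- params$b[(h + 1):(2 * h)]
  bg <- params$b[(2 * h + 1):(3 * h)]; bo <- params$b[(3 * h + 1):(4 * h)]
  sig <- function(z) 1 / (1 + exp(-z))
  hh <- rep(0, h); cc <- rep(0, h)
  for (ix in idx0) {
    x <- params$E[ix + 1, ]
    i_t <- sig(as.vector(x %*% Wi) + as.vector(hh %*% Ui) + bi)
    f_t <- sig(as.vector(x %*% Wf) + as.vector(hh %*% Uf) + bf)
    g_t <- tanh(as.vector(x %*% Wg) + as.vector(hh %*% Ug) + bg)
    o_t <- sig(as.vector(x %*% Wo) + as.vector(hh %*% Uo) + bo)
    cc <- f_t * cc + i_t * g_t
    hh <- o_t * tanh(cc)
  }
  sig(sum(hh * params$w_out) + params$b_out)
}

toy_params <- function(vocab, d = 2, h = 2, seed = 4) {
  emb <- make_embedding(vocab, dim = d)
  p <- lstm_params(emb, hidden_size = h, init = "zero")
  set.seed(seed)
  p$W <- matrix(runif(d * 4 * h, -0.5, 0.5), d, 4 * h)
  p$U <- matrix(runif(h * 4 * h, -0.5, 0.5), h, 4 * h)
  p$b <- runif(4 * h, -0.2, 0.2)
  p$w_out <- runif(h, -1, 1)
  p$b_out <- 0.3
  p
}
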