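#' Class weights for imbalanced binary training
#'
#' The minority (PET) class is weighted by the ratio of majority to minority
#' instance counts, and the majority class by the inverse ratio, so each
#' misclassified minority example costs proportionally more.
#'
#' @param n_pos Number of positive (PET) training instances.
#' @param n_neg Number of negative (non-PET) training instances.
#' @return A `pet_class_weights` object with elements `w_pos` and `w_neg`.
#' @export
#' @examples
#' compute_class_weights(2650, 6547)  # w_pos ~ 2.47, w_neg ~ 0.40
compute_class_weights <- function(n_pos, n_neg) {
  if (!is.numeric(n_pos) || !is.numeric(n_neg) || n_pos <= 0 || n_neg <= 0) {
    abort("Both class counts must be positive to derive class weights")
  }
  structure(list(w_pos = n_neg / n_pos, w_neg = n_pos / n_neg),
            class = "pet_class_weights")
}

#' @exportS3Method base::print
print.pet_class_weights <- function(x, ...) {
  cat(sprintf("<pet_class_weights> w_pos (PET) = %.6g, w_neg (non-PET) = %.6g\n",
              x$w_pos, x$w_neg))
  invisible(x)
}

#' Construct an LSTM parameter set
#'
#' Builds the parameter arrays of the classifier: the embedding layer
#' (initialised from a pretrained embedding matrix), the LSTM gate and
#' recurrent weights with the gate blocks ordered (input, forget, candidate,
#' output), the gate biases (forget bias initialised to 1), and the
#' single-unit dense output head.
#'
#' @param embedding A `pet_embedding`, or a bare V x d numeric matrix whose
#'   row 1 is the pad row.
#' @param hidden_size LSTM hidden state width `h` (default 128).
#' @param init `"glorot"` for uniform Glorot initialisation of the gate /
#'   recurrent / output weights, `"zero"` for all-zero (useful for tests and
#'   closed-form checks).
#' @param seed Seed for the random initialisation.
#' @return A `pet_lstm_params` list with elements `E` (V x d), `W` (d x 4h),
#'   `U` (h x 4h), `b` (4h), `w_out` (h), `b_out`, and the dimensions.
#' @export
lstm_params <- function(embedding, hidden_size = 128L,
                        init = c("glorot", "zero"), seed = 0L) {
  init <- match.arg(init)
  E <- if (inherits(embedding, "pet_embedding")) embedding$vectors else embedding
  stopifnot(is.matrix(E), hidden_size >= 1)
  d <- ncol(E)
  h <- as.integer(hidden_size)

  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -r, r), nr, nc)
  }
  params <- with_seed(seed, {
    if (init == "glorot") {
      W <- glorot(d, 4L * h)
      U <- glorot(h, 4L * h)
      w_out <- as.vector(glorot(h, 1L))
    } else {
      W <- matrix(0, d, 4L * h)
      U <- matrix(0, h, 4L * h)
      w_out <- numeric(h)
    }
    b <- numeric(4L * h)
    b[(h + 1L):(2L * h)] <- if (init == "glorot") 1 else 0  # forget-gate bias
    list(E = E, W = W, U = U, b = b, w_out = w_out, b_out = 0,
         d = d, h = h, V = nrow(E))
  })
  structure(params, class = "pet_lstm_params")
}

gate_cols <- function(h) {
  list(i = 1:h, f = (h + 1):(2 * h), g = (2 * h + 1):(3 * h),
       o = (3 * h + 1):(4 * h))
}

#' LSTM forward pass
#'
#' Runs the gated recurrence over an embedded index sequence and returns the
#' PET probability from the sigmoid output head. Per step `t` with embedded
#' input `x_t`: input gate `i_t = sigma(x_t W_i + h_{t-1} U_i + b_i)`, forget
#' gate `f_t`, output gate `o_t` analogously, candidate
#' `g_t = tanh(x_t W_c + h_{t-1} U_c + b_c)`, cell
#' `c_t = f_t * c_{t-1} + i_t * g_t`, hidden `h_t = o_t * tanh(c_t)`, with
#' `h_0 = c_0 = 0`. The probability is `sigma(h_T . w_out + b_out)` where `T`
#' is the final step (`max_len`), or step `true_length` per sequence in
#' masked-readout mode.
#'
#' @param params A `pet_lstm_params`, or a fitted `pet_lstm` model.
#' @param indices Integer vector (one padded sequence, 0-based indices) or an
#'   n x max_len matrix of such sequences.
#' @param true_length Integer vector of pre-padding lengths; required when
#'   `masked = TRUE`.
#' @param masked If `TRUE`, read the hidden state at `true_length` instead of
#'   at the final step, making the output invariant to padding.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
lstm_forward <- function(params, indices, true_length = NULL, masked = FALSE) {
  if (inherits(params, "pet_lstm")) params <- params$params
  stopifnot(inherits(params, "pet_lstm_params"))
  X <- if (is.matrix(indices)) indices else matrix(indices, nrow = 1)
  out <- lstm_forward_batch(params, X, true_length = true_length,
                            masked = masked, keep_cache = FALSE)
  if (any(!is.finite(out$p))) abort("Non-finite value in LSTM forward pass")
  out$p
}

# Batched forward over an n x T index matrix; optionally caches every
# intermediate needed for backpropagation through time.
lstm_forward_batch <- function(params, X, true_length = NULL, masked = FALSE,
                               keep_cache = FALSE) {
  B <- nrow(X); Tn <- ncol(X)
  h <- params$h
  gc_ <- gate_cols(h)
  if (masked && is.null(true_length)) {
    abort("masked readout requires true_length")
  }
  H <- matrix(0, B, h); C <- matrix(0, B, h)
  H_out <- matrix(0, B, h)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  b_rep <- rep(params$b, each = B)

  for (t in seq_len(Tn)) {
    idx <- X[, t] + 1L
    Xt <- params$E[idx, , drop = FALSE]
    Z <- Xt %*% params$W + H %*% params$U + b_rep
    i_g <- sigmoid(Z[, gc_$i, drop = FALSE])
    f_g <- sigmoid(Z[, gc_$f, drop = FALSE])
    g_g <- tanh(Z[, gc_$g, drop = FALSE])
    o_g <- sigmoid(Z[, gc_$o, drop = FALSE])
    C_new <- f_g * C + i_g * g_g
    tc <- tanh(C_new)
    H_new <- o_g * tc
    if (keep_cache) {
      cache[[t]] <- list(idx = idx, Xt = Xt, i = i_g, f = f_g, g = g_g,
                         o = o_g, c_prev = C, tc = tc, h_prev = H)
    }
    H <- H_new; C <- C_new
    if (masked) {
      hit <- which(true_length == t)
      if (length(hit)) H_out[hit, ] <- H[hit, , drop = FALSE]
    }
  }
  if (!masked) H_out <- H
  logit <- as.vector(H_out %*% params$w_out) + params$b_out
  list(p = sigmoid(logit), H_out = H_out, cache = cache, Tn = Tn, B = B)
}

#' Class-weighted cross-entropy loss
#'
#' Per-example term `-(w_pos * y * log p + w_neg * (1 - y) * log(1 - p))`;
#' the batch loss is the mean of per-example terms plus
#' `l2_lambda * (sum(W^2) + sum(U^2))` over the LSTM-layer gate and recurrent
#' weights (biases and the embedding are not penalised). Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param p Predicted probabilities.
#' @param y 0/1 labels (1 = PET) or `"PET"`/`"nonPET"` characters.
#' @param weights A `pet_class_weights` (default: unweighted).
#' @param params Optional `pet_lstm_params` contributing the L2 penalty.
#' @param l2_lambda L2 coefficient (default 0).
#' @return Scalar loss.
#' @export
weighted_loss <- function(p, y, weights = compute_class_weights(1, 1),
                          params = NULL, l2_lambda = 0) {
  y <- as_binary_label(y)
  stopifnot(length(p) == length(y))
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  per <- -(weights$w_pos * y * log(p) + weights$w_neg * (1 - y) * log(1 - p))
  loss <- mean(per)
  if (!is.null(params) && l2_lambda > 0) {
    loss <- loss + l2_lambda * (sum(params$W^2) + sum(params$U^2))
  }
  loss
}

# Loss and analytic gradients for one batch (backpropagation through time).
# Returns list(loss, grads); grads has the same shapes as the parameters.
# The pad embedding row is frozen: its gradient is zeroed.
lstm_loss_grads <- function(params, X, y, weights, l2_lambda = 0,
                            true_length = NULL, masked = FALSE) {
  fwd <- lstm_forward_batch(params, X, true_length = true_length,
                            masked = masked, keep_cache = TRUE)
  B <- fwd$B; Tn <- fwd$Tn
  h <- params$h
  gc_ <- gate_cols(h)
  p <- fwd$p
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  wvec <- ifelse(y == 1, weights$w_pos, weights$w_neg)
  loss <- mean(-(weights$w_pos * y * log(pc) +
                   weights$w_neg * (1 - y) * log(1 - pc))) +
    l2_lambda * (sum(params$W^2) + sum(params$U^2))

  dlogit <- wvec * (p - y) / B
  g_w_out <- as.vector(t(fwd$H_out) %*% dlogit)
  g_b_out <- sum(dlogit)
  dH_inject <- outer(dlogit, params$w_out)  # B x h

  gW <- matrix(0, params$d, 4 * h)
  gU <- matrix(0, h, 4 * h)
  gb <- numeric(4 * h)
  dH <- matrix(0, B, h)
  dC <- matrix(0, B, h)
  idx_all <- integer(B * Tn)
  dX_all <- matrix(0, B * Tn, params$d)

  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    if (masked) {
      hit <- which(true_length == t)
      if (length(hit)) dH[hit, ] <- dH[hit, , drop = FALSE] +
          dH_inject[hit, , drop = FALSE]
    } else if (t == Tn) {
      dH <- dH + dH_inject
    }
    do_ <- dH * cc$tc
    dCt <- dC + dH * cc$o * (1 - cc$tc^2)
    di <- dCt * cc$g
    dg <- dCt * cc$i
    df <- dCt * cc$c_prev
    dC <- dCt * cc$f
    dZ <- matrix(0, B, 4 * h)
    dZ[, gc_$i] <- di * cc$i * (1 - cc$i)
    dZ[, gc_$f] <- df * cc$f * (1 - cc$f)
    dZ[, gc_$g] <- dg * (1 - cc$g^2)
    dZ[, gc_$o] <- do_ * cc$o * (1 - cc$o)
    gW <- gW + t(cc$Xt) %*% dZ
    gU <- gU + t(cc$h_prev) %*% dZ
    gb <- gb + colSums(dZ)
    dH <- dZ %*% t(params$U)
    rows <- ((t - 1L) * B + 1L):(t * B)
    idx_all[rows] <- cc$idx
    dX_all[rows, ] <- dZ %*% t(params$W)
  }

  gW <- gW + 2 * l2_lambda * params$W
  gU <- gU + 2 * l2_lambda * params$U

  gE <- matrix(0, params$V, params$d)
  agg <- rowsum(dX_all, group = idx_all)
  gE[as.integer(rownames(agg)), ] <- agg
  gE[PAD_INDEX + 1L, ] <- 0  # pad row frozen

  list(loss = loss,
       grads = list(E = gE, W = gW, U = gU, b = gb,
                    w_out = g_w_out, b_out = g_b_out))
}

#' Train the class-weighted LSTM classifier
#'
#' Fits the embedding -> LSTM -> dense-sigmoid classifier by adaptive-moment
#' (Adam) gradient descent on the class-weighted cross-entropy of
#' [weighted_loss()], with L2 regularisation on the LSTM gate and recurrent
#' weights. The embedding layer is initialised from the pretrained vectors
#' and fine-tuned jointly (set `finetune_embedding = FALSE` to freeze it).
#' The last `val_fraction` of a seeded shuffle of the data is held out for
#' per-epoch validation logging; class weights default to the
#' majority/minority count ratio of the remaining training portion. Training
#' is deterministic for a fixed seed under single-threaded execution.
#'
#' @param encoded A labeled `pet_encoded` tibble (column `label` required).
#' @param embedding The pretrained `pet_embedding` matching the vocabulary
#'   used to encode `encoded`.
#' @param hidden_size LSTM hidden width (default 128).
#' @param epochs Training epochs (default 5).
#' @param l2_lambda L2 coefficient on LSTM weights (default 0.01).
#' @param val_fraction Fraction held out for validation logging (default
#'   0.30; may be 0).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 0.001).
#' @param threshold Decision threshold stored with the model (default 0.5;
#'   label is PET iff probability >= threshold).
#' @param class_weights Optional `pet_class_weights`; default derived from
#'   the training portion.
#' @param masked_readout If `TRUE`, read the hidden state at each sequence's
#'   true length instead of the final padded step.
#' @param finetune_embedding Whether the embedding layer is updated during
#'   training (default `TRUE`).
#' @param seed Integer seed controlling the shuffle, initialisation and batch
#'   order.
#' @param verbose Print per-epoch losses.
#' @return A fitted `pet_lstm` model with elements `params`, `config`,
#'   `history` (per-epoch tibble) and the vocabulary reference.
#' @export
fit_pet_lstm <- function(encoded, embedding, hidden_size = 128L, epochs = 5L,
                         l2_lambda = 0.01, val_fraction = 0.30,
                         batch_size = 32L, learning_rate = 0.001,
                         threshold = 0.5, class_weights = NULL,
                         masked_readout = FALSE, finetune_embedding = TRUE,
                         seed = 0L, verbose = FALSE) {
  stopifnot(inherits(encoded, "pet_encoded"), inherits(embedding, "pet_embedding"))
  check_column(encoded, "label", "training data")
  if (!is.numeric(epochs) || epochs < 1) {
    abort("epochs must be a positive integer")
  }
  if (val_fraction < 0 || val_fraction >= 1) {
    abort("val_fraction must be in [0, 1)")
  }
  y <- as_binary_label(encoded$label)
  if (length(unique(y)) < 2) {
    abort("Training data must contain both classes")
  }
  X <- encoded_matrix(encoded)
  tl <- encoded$true_length
  n <- nrow(X)

  with_seed(seed, {
    perm <- sample(n)
    n_val <- floor(val_fraction * n)
    val_idx <- if (n_val > 0) perm[(n - n_val + 1L):n] else integer(0)
    tr_idx <- perm[seq_len(n - n_val)]
    if (length(unique(y[tr_idx])) < 2) {
      abort("Training portion has a single class after the validation split")
    }
    if (is.null(class_weights)) {
      class_weights <- compute_class_weights(sum(y[tr_idx] == 1),
                                             sum(y[tr_idx] == 0))
    }

    params <- lstm_params(embedding, hidden_size = hidden_size,
                          init = "glorot",
                          seed = sample.int(.Machine$integer.max, 1))
    opt <- adam_state(params)
    history <- vector("list", epochs)

    for (ep in seq_len(epochs)) {
      order_ep <- sample(tr_idx)
      batch_losses <- c()
      for (start in seq(1, length(order_ep), by = batch_size)) {
        bi <- order_ep[start:min(start + batch_size - 1L, length(order_ep))]
        gr <- lstm_loss_grads(params, X[bi, , drop = FALSE], y[bi],
                              class_weights, l2_lambda,
                              true_length = tl[bi], masked = masked_readout)
        if (!is.finite(gr$loss)) abort("Non-finite training loss")
        upd <- adam_step(params, gr$grads, opt, learning_rate,
                         update_embedding = finetune_embedding)
        params <- upd$params; opt <- upd$state
        batch_losses <- c(batch_losses, gr$loss)
      }
      ep_row <- tibble(epoch = ep, train_loss = mean(batch_losses),
                       val_loss = NA_real_, val_accuracy = NA_real_)
      if (length(val_idx)) {
        pv <- lstm_forward(params, X[val_idx, , drop = FALSE],
                           true_length = tl[val_idx], masked = masked_readout)
        ep_row$val_loss <- weighted_loss(pv, y[val_idx], class_weights,
                                         params, l2_lambda)
        ep_row$val_accuracy <- mean((pv >= threshold) == (y[val_idx] == 1))
      }
      if (verbose) {
        inform(sprintf("epoch %d: train_loss %.4f val_acc %s", ep,
                       ep_row$train_loss,
                       ifelse(is.na(ep_row$val_accuracy), "-",
                              sprintf("%.3f", ep_row$val_accuracy))))
      }
      history[[ep]] <- ep_row
    }

    structure(
      list(
        params = params,
        config = list(hidden_size = as.integer(hidden_size),
                      epochs = as.integer(epochs), l2_lambda = l2_lambda,
                      val_fraction = val_fraction,
                      batch_size = as.integer(batch_size),
                      learning_rate = learning_rate, threshold = threshold,
                      masked_readout = masked_readout,
                      finetune_embedding = finetune_embedding,
                      seed = as.integer(seed),
                      max_len = attr(encoded, "max_len")),
        class_weights = class_weights,
        history = dplyr::bind_rows(history),
        vocab = embedding$vocab
      ),
      class = "pet_lstm"
    )
  })
}

adam_state <- function(params) {
  z <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else
    numeric(length(x))
  groups <- c("E", "W", "U", "b", "w_out", "b_out")
  list(m = map(setNames(groups, groups), function(g) z(params[[g]])),
       v = map(setNames(groups, groups), function(g) z(params[[g]])),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, update_embedding = TRUE) {
  state$t <- state$t + 1L
  groups <- c(if (update_embedding) "E", "W", "U", "b", "w_out", "b_out")
  for (g in groups) {
    state$m[[g]] <- beta1 * state$m[[g]] + (1 - beta1) * grads[[g]]
    state$v[[g]] <- beta2 * state$v[[g]] + (1 - beta2) * grads[[g]]^2
    mhat <- state$m[[g]] / (1 - beta1^state$t)
    vhat <- state$v[[g]] / (1 - beta2^state$t)
    params[[g]] <- params[[g]] - lr * mhat / (sqrt(vhat) + eps)
  }
  if (update_embedding) params$E[PAD_INDEX + 1L, ] <- 0  # keep pad frozen
  list(params = params, state = state)
}

#' Predict PET probabilities and labels
#'
#' @param object A fitted `pet_lstm`.
#' @param newdata A `pet_encoded` tibble encoded against the model's
#'   vocabulary.
#' @param threshold Decision threshold; label is PET iff probability
#'   `>= threshold` (default: the model's configured threshold).
#' @param ... Unused.
#' @return A tibble with columns `tweet_id`, `probability`, `label`.
#' @export
predict.pet_lstm <- function(object, newdata, threshold = NULL, ...) {
  stopifnot(inherits(newdata, "pet_encoded"))
  threshold <- threshold %||% object$config$threshold
  X <- encoded_matrix(newdata)
  p <- lstm_forward(object$params, X, true_length = newdata$true_length,
                    masked = object$config$masked_readout)
  tibble(tweet_id = newdata$tweet_id, probability = p,
         label = binary_to_label(as.integer(p >= threshold)))
}

#' @exportS3Method base::print
print.pet_lstm <- function(x, ...) {
  cat(sprintf(
    "<pet_lstm> h = %d, d = %d, V = %d; %d epoch(s), l2 = %g, w_pos = %.3f\n",
    x$config$hidden_size, x$params$d, x$params$V, x$config$epochs,
    x$config$l2_lambda, x$class_weights$w_pos
  ))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train_loss %.4f%s\n", last$train_loss,
              if (!is.na(last$val_accuracy)) {
                sprintf(", val_accuracy %.3f", last$val_accuracy)
              } else ""))
  invisible(x)
}

#' Save / load a fitted LSTM model as JSON
#'
#' A single versioned text archive holding every parameter array, the
#' training configuration, the class weights, the training history and the
#' vocabulary.
#'
#' @param model A `pet_lstm`.
#' @param path File path.
#' @return `read_pet_lstm()` returns the restored `pet_lstm`.
#' @export
write_pet_lstm <- function(model, path) {
  stopifnot(inherits(model, "pet_lstm"))
  payload <- list(
    format = "petminer-lstm", version = 1L,
    config = model$config,
    class_weights = unclass(model$class_weights),
    history = model$history,
    vocab_terms = model$vocab$terms,
    params = list(E = model$params$E, W = model$params$W, U = model$params$U,
                  b = model$params$b, w_out = model$params$w_out,
                  b_out = model$params$b_out, d = model$params$d,
                  h = model$params$h, V = model$params$V)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pet_lstm
#' @export
read_pet_lstm <- function(path) {
  pl <- jsonlite::fromJSON(path)
  if (!identical(pl$format, "petminer-lstm")) abort("Not a petminer LSTM archive")
  params <- structure(
    list(E = as.matrix(pl$params$E), W = as.matrix(pl$params$W),
         U = as.matrix(pl$params$U), b = as.numeric(pl$params$b),
         w_out = as.numeric(pl$params$w_out),
         b_out = as.numeric(pl$params$b_out),
         d = as.integer(pl$params$d), h = as.integer(pl$params$h),
         V = as.integer(pl$params$V)),
    class = "pet_lstm_params"
  )
  structure(
    list(params = params, config = pl$config,
         class_weights = structure(pl$class_weights,
                                   class = "pet_class_weights"),
         history = as_tibble(pl$history),
         vocab = new_pet_vocab(pl$vocab_terms)),
    class = "pet_lstm"
  )
}
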