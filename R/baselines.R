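#' Bag-of-words vectorization
#'
#' Represents each tweet as a sparse vector of word occurrence counts over a
#' vocabulary built from the supplied (labeled) corpus only — no reserved
#' `pad`/`unk` entries, terms in lexicographic order. Token order within a
#' tweet is irrelevant by construction.
#'
#' @param sequences Tokenized corpus (tibble with `tweet_id` + `tokens`
#'   columns, or bare list of token vectors).
#' @param binary If `TRUE`, store presence indicators instead of counts.
#' @return A sparse `dgCMatrix` (rows = tweets, columns = terms in
#'   lexicographic order); `colnames()` is the corpus vocabulary.
#' @export
#' @examples
#' bow <- bow_vectorize(list(c("a", "b", "a")))
#' as.matrix(bow)
bow_vectorize <- function(sequences, binary = FALSE) {
  is_df <- is.data.frame(sequences)
  seqs <- token_list(sequences)
  if (length(seqs) == 0 || sum(map_int(seqs, length)) == 0) {
    abort("Cannot vectorize an empty corpus")
  }
  terms <- sort(unique(unlist(seqs, use.names = FALSE)), method = "radix")
  ids <- if (is_df && "tweet_id" %in% names(sequences)) {
    as.character(sequences$tweet_id)
  } else {
    as.character(seq_along(seqs))
  }
  M <- bow_count_matrix(seqs, terms, ids)
  if (binary) M@x <- rep(1, length(M@x))
  M
}

# Count matrix of seqs over a fixed term vector (unknown tokens dropped).
bow_count_matrix <- function(seqs, terms, ids) {
  n_tok <- map_int(seqs, length)
  row_idx <- rep.int(seq_along(seqs), n_tok)
  col_idx <- match(unlist(seqs, use.names = FALSE), terms)
  keep <- !is.na(col_idx)
  M <- Matrix::sparseMatrix(
    i = row_idx[keep], j = col_idx[keep], x = 1,
    dims = c(length(seqs), length(terms)),
    dimnames = list(ids, terms)
  )
  methods::as(M, "CsparseMatrix")
}

#' Project a new tokenized corpus onto an existing BoW vocabulary
#'
#' Terms unseen in the vocabulary the model was fitted on are dropped —
#' exactly what happens at test time under cross-validation.
#'
#' @param sequences Tokenized corpus.
#' @param terms Character vector of vocabulary terms (e.g. `colnames(bow)`).
#' @param binary Presence indicators instead of counts.
#' @return A sparse matrix with `length(terms)` columns.
#' @export
bow_project <- function(sequences, terms, binary = FALSE) {
  is_df <- is.data.frame(sequences)
  seqs <- token_list(sequences)
  ids <- if (is_df && "tweet_id" %in% names(sequences)) {
    as.character(sequences$tweet_id)
  } else {
    as.character(seq_along(seqs))
  }
  M <- bow_count_matrix(seqs, terms, ids)
  if (binary) M@x <- rep(1, length(M@x))
  M
}

#' Fit the L2-penalised logistic-regression baseline
#'
#' Ridge-penalised logistic maximum likelihood on sparse BoW vectors, with
#' the penalty expressed through the inverse-regularisation constant `C`
#' (larger `C`, weaker penalty; the ridge weight is `1 / (C * n)`). The
#' problem is convex, so the fit is deterministic; `seed` is stored for
#' provenance.
#'
#' @param X A BoW matrix from [bow_vectorize()] (or any numeric/sparse
#'   matrix with named columns).
#' @param y Labels (`"PET"`/`"nonPET"`, factor, or 0/1).
#' @param C Inverse regularisation strength (default 1000).
#' @param seed Stored with the model (default 0).
#' @return A `pet_logreg` with `coefficients`, `intercept`, `C`, and the
#'   training term vector.
#' @export
fit_logreg <- function(X, y, C = 1000, seed = 0L) {
  y <- as_binary_label(y)
  stopifnot(nrow(X) == length(y), C > 0)
  if (length(unique(y)) < 2) {
    abort("Logistic regression requires both classes in y")
  }
  Xs <- methods::as(X, "CsparseMatrix")
  p <- ncol(Xs)
  if (p == 1) {
    # the ridge solver requires >= 2 columns; a zero dummy changes nothing
    Xs <- cbind(Xs, Matrix::Matrix(0, nrow(Xs), 1, sparse = TRUE))
  }
  fit <- glmnet::glmnet(
    Xs, y, family = "binomial", alpha = 0,
    lambda = 1 / (C * nrow(Xs)),
    standardize = FALSE, thresh = 1e-10, maxit = 1e6
  )
  structure(
    list(
      coefficients = as.numeric(fit$beta[, 1])[seq_len(p)],
      intercept = as.numeric(fit$a0[1]),
      C = C, seed = as.integer(seed),
      terms = colnames(X)
    ),
    class = "pet_logreg"
  )
}

#' @exportS3Method base::print
print.pet_logreg <- function(x, ...) {
  cat(sprintf("<pet_logreg> %d features, C = %g, intercept = %.4g\n",
              length(x$coefficients), x$C, x$intercept))
  invisible(x)
}

#' @param object A `pet_logreg`.
#' @param newdata Matrix with columns aligned to the training terms, or a
#'   tokenized corpus (projected via [bow_project()]).
#' @param threshold Decision threshold (default 0.5).
#' @param ... Unused.
#' @rdname fit_logreg
#' @export
predict.pet_logreg <- function(object, newdata, threshold = 0.5, ...) {
  if (!is.matrix(newdata) && !inherits(newdata, "Matrix")) {
    newdata <- bow_project(newdata, object$terms)
  }
  stopifnot(ncol(newdata) == length(object$coefficients))
  eta <- as.numeric(newdata %*% object$coefficients) + object$intercept
  p <- sigmoid(eta)
  ids <- rownames(newdata) %||% as.character(seq_len(nrow(newdata)))
  tibble(tweet_id = ids, probability = p,
         label = binary_to_label(as.integer(p >= threshold)))
}

#' Cross-validated harness for externally supplied feature tables
#'
#' Fits one of the conventional classifiers on a caller-supplied numeric
#' feature table (for example hand-engineered tweet features) and returns
#' per-fold held-out predictions. The supported classifiers and their default
#' settings mirror a scikit-learn-style configuration: `"logreg"`
#' (L2-penalised, `C = 1`), `"tree"` (entropy splits, depth at most 30,
#' minimum split 2, minimum leaf 1), `"knn"` (`k = 1`, Euclidean), `"svm"`
#' (RBF kernel, `cost = 1`, `gamma = 0.001`). The engineered features
#' themselves are not computed here.
#'
#' @param features A numeric data frame / matrix, rows aligned with `y`.
#' @param y Labels.
#' @param classifier One of `"logreg"`, `"tree"`, `"knn"`, `"svm"`.
#' @param settings Named list overriding classifier defaults
#'   (e.g. `list(k = 3)` for knn, `list(C = 10)` for logreg).
#' @param folds A fold assignment from [kfold_split()]; `NULL` fits on all
#'   rows and predicts the same rows (resubstitution).
#' @return A tibble of predictions with columns `id`, `fold` (NA for
#'   resubstitution), `probability`, `label`, plus the true label as
#'   `truth`.
#' @export
external_feature_harness <- function(features, y,
                                     classifier = c("logreg", "tree", "knn", "svm"),
                                     settings = list(), folds = NULL) {
  supported <- c("logreg", "tree", "knn", "svm")
  if (length(classifier) == 1 && !classifier %in% supported) {
    abort(sprintf("Unknown classifier '%s'; supported: %s",
                  classifier, paste(supported, collapse = ", ")))
  }
  classifier <- match.arg(classifier)
  features <- as.data.frame(features)
  if (nrow(features) == 0 || ncol(features) == 0) {
    abort("Empty feature table")
  }
  y01 <- as_binary_label(y)
  stopifnot(nrow(features) == length(y01))
  method <- feature_method(classifier, settings)

  run_split <- function(tr, te, fold) {
    model <- method$fit(features[tr, , drop = FALSE], y01[tr])
    pred <- method$predict(model, features[te, , drop = FALSE])
    tibble(id = as.character(te), fold = fold,
           probability = pred$probability, label = pred$label,
           truth = binary_to_label(y01[te]))
  }

  if (is.null(folds)) {
    run_split(seq_along(y01), seq_along(y01), NA_integer_)
  } else {
    idx <- seq_along(y01)
    fold_of <- folds$fold[match(as.character(idx), folds$id)]
    if (any(is.na(fold_of))) {
      abort("Fold assignment does not cover all feature rows (ids must be row numbers)")
    }
    bind_rows(map(sort(unique(fold_of)), function(f) {
      run_split(idx[fold_of != f], idx[fold_of == f], f)
    }))
  }
}

# Train/predict closures for the conventional classifiers.
feature_method <- function(classifier, settings = list()) {
  switch(classifier,
    logreg = {
      cfg <- modifyList(list(C = 1), settings)
      list(
        fit = function(X, y) fit_logreg(as.matrix(X), y, C = cfg$C),
        predict = function(m, X) predict(m, as.matrix(X))
      )
    },
    tree = {
      cfg <- modifyList(list(max_depth = 30, min_split = 2, min_leaf = 1),
                        settings)
      list(
        fit = function(X, y) {
          entropy_tree_fit(as.matrix(X), y, max_depth = cfg$max_depth,
                           min_split = cfg$min_split, min_leaf = cfg$min_leaf)
        },
        predict = function(m, X) {
          p <- entropy_tree_predict(m, as.matrix(X))
          tibble(probability = p,
                 label = binary_to_label(as.integer(p >= 0.5)))
        }
      )
    },
    knn = {
      cfg <- modifyList(list(k = 1), settings)
      list(
        fit = function(X, y) list(X = as.matrix(X), y = y, k = cfg$k),
        predict = function(m, X) {
          pr <- class::knn(m$X, as.matrix(X), factor(m$y, levels = c(0, 1)),
                           k = m$k, prob = TRUE)
          vote <- attr(pr, "prob")
          p <- ifelse(pr == "1", vote, 1 - vote)
          tibble(probability = p, label = binary_to_label(as.integer(pr == "1")))
        }
      )
    },
    svm = {
      cfg <- modifyList(list(cost = 1, gamma = 0.001, tolerance = 1e-4),
                        settings)
      list(
        fit = function(X, y) {
          e1071::svm(as.matrix(X), factor(y, levels = c(0, 1)),
                     kernel = "radial", cost = cfg$cost, gamma = cfg$gamma,
                     tolerance = cfg$tolerance, probability = TRUE)
        },
        predict = function(m, X) {
          pr <- predict(m, as.matrix(X), probability = TRUE)
          p <- attr(pr, "probabilities")[, "1"]
          tibble(probability = as.numeric(p),
                 label = binary_to_label(as.integer(pr == "1")))
        }
      )
    }
  )
}

# Greedy binary decision tree with entropy (information-gain) splits.
# Grows like the reference configuration it mirrors: the best midpoint split
# is taken even when its gain is zero, so the fully grown tree memorises any
# consistent training set (e.g. XOR) within the depth cap. Off-the-shelf
# recursive-partitioning fits refuse zero-gain splits and cannot do this.
entropy_tree_fit <- function(X, y, max_depth = 30, min_split = 2,
                             min_leaf = 1, depth = 0) {
  n <- length(y)
  prob <- mean(y)
  leaf <- list(leaf = TRUE, prob = prob)
  if (depth >= max_depth || n < min_split || prob == 0 || prob == 1) {
    return(leaf)
  }
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  node_H <- H(c(prob, 1 - prob))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    cuts <- sort(unique(v))
    if (length(cuts) < 2) next
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (thr in mids) {
      left <- v <= thr
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      pl <- mean(y[left]); pr <- mean(y[!left])
      gain <- node_H - (nl * H(c(pl, 1 - pl)) +
                          (n - nl) * H(c(pr, 1 - pr))) / n
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(j = j, thr = thr, gain = gain, left = left)
      }
    }
  }
  if (is.null(best)) return(leaf)
  list(
    leaf = FALSE, j = best$j, thr = best$thr,
    left = entropy_tree_fit(X[best$left, , drop = FALSE], y[best$left],
                            max_depth, min_split, min_leaf, depth + 1),
    right = entropy_tree_fit(X[!best$left, , drop = FALSE], y[!best$left],
                             max_depth, min_split, min_leaf, depth + 1)
  )
}

entropy_tree_predict <- function(node, X) {
  vapply(seq_len(nrow(X)), function(i) {
    nd <- node
    while (!nd$leaf) {
      nd <- if (X[i, nd$j] <= nd$thr) nd$left else nd$right
    }
    nd$prob
  }, 0)
}
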