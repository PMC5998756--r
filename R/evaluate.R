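#' k-fold cross-validation assignment
#'
#' Seeded shuffle followed by round-robin fold assignment. With
#' `stratify_labels`, assignment is round-robin within each class — with the
#' starting fold staggered between classes — so per-fold class counts differ
#' by at most one example and total fold sizes still differ by at most one.
#'
#' @param ids Vector of example identifiers (coerced to character; must be
#'   unique).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param stratify_labels Optional label vector aligned with `ids`.
#' @return A `pet_folds` tibble with columns `id` and `fold` (0-based), and
#'   attributes `k` and `seed`.
#' @export
kfold_split <- function(ids, k = 10L, seed = 1L, stratify_labels = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) abort("ids must be unique")
  if (k < 2) abort("k must be at least 2")
  if (k > n) abort(sprintf("k = %d exceeds the number of examples (%d)", k, n))

  fold <- integer(n)
  with_seed(seed, {
    if (is.null(stratify_labels)) {
      perm <- sample(n)
      fold[perm] <- (seq_len(n) - 1L) %% k
    } else {
      stopifnot(length(stratify_labels) == n)
      offset <- 0L
      for (cl in sort(unique(as.character(stratify_labels)))) {
        rows <- which(as.character(stratify_labels) == cl)
        perm <- rows[sample(length(rows))]
        fold[perm] <- (offset + seq_along(rows) - 1L) %% k
        offset <- (offset + length(rows)) %% k
      }
    }
  })
  structure(tibble(id = ids, fold = fold),
            class = c("pet_folds", class(tibble())),
            k = as.integer(k), seed = as.integer(seed))
}

#' Classification performance measures
#'
#' Computes the five standard measures for the PET (positive) class:
#' accuracy, precision, recall, F1, and ROC/AUC. AUC uses the rank
#' (Mann-Whitney) formulation — the fraction of (positive, negative) pairs in
#' which the positive scores higher, ties counting one half — which equals
#' exhaustive pair counting exactly. Undefined precision or recall (zero
#' denominator) is reported as 0 with a warning so fold vectors stay aligned
#' for paired testing.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param y_score Predicted positive-class scores/probabilities (for AUC);
#'   `NULL` yields `NA` AUC.
#' @return A one-row tibble with columns `accuracy`, `precision_pet`,
#'   `recall_pet`, `f1_pet`, `roc_auc`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0), c(.9, .4, .6, .1))
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  yt <- as_binary_label(y_true)
  yp <- as_binary_label(y_pred)
  stopifnot(length(yt) == length(yp))
  tp <- sum(yt == 1 & yp == 1)
  fp <- sum(yt == 0 & yp == 1)
  fn <- sum(yt == 1 & yp == 0)
  tn <- sum(yt == 0 & yp == 0)

  zero_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); reported as 0", what))
      0
    } else {
      num / den
    }
  }
  precision <- zero_div(tp, tp + fp, "Precision")
  recall <- zero_div(tp, tp + fn, "Recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)

  auc <- if (is.null(y_score)) NA_real_ else roc_auc(yt, y_score)
  tibble(accuracy = (tp + tn) / length(yt),
         precision_pet = precision, recall_pet = recall, f1_pet = f1,
         roc_auc = auc)
}

#' ROC/AUC by the rank formulation
#'
#' @param y_true 0/1 (or PET/nonPET) labels.
#' @param y_score Numeric scores.
#' @return AUC in \[0, 1\]; `NA` with a warning if either class is absent.
#' @export
roc_auc <- function(y_true, y_score) {
  yt <- as_binary_label(y_true)
  stopifnot(length(yt) == length(y_score))
  np <- sum(yt == 1); nn <- sum(yt == 0)
  if (np == 0 || nn == 0) {
    warn("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(y_score, ties.method = "average")
  (sum(r[yt == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validate a classification method
#'
#' Runs the k-fold protocol: for each fold, trains the method on the other
#' folds and evaluates on the held-out fold. Methods are train/predict
#' contracts (see [lstm_method()], [bow_method()], [feature_table_method()]),
#' so different methods can be compared on *identical* fold assignments —
#' the precondition for a valid fold-paired t-test. Folds lacking positive
#' examples are flagged in the output rather than silently averaged.
#'
#' @param data A tibble the method understands; must carry an `id` column
#'   matching `folds$id` and a `label` column.
#' @param folds A `pet_folds` assignment covering `data`.
#' @param method A method contract: `list(name, fit(data), predict(model,
#'   data))` where `predict` returns a tibble with `probability` and `label`.
#' @return A `pet_cv` object: per-fold metrics (tibble with `fold`, the five
#'   measures, and `flagged`), their means, and the fold assignment.
#' @export
cross_validate <- function(data, folds, method) {
  stopifnot(inherits(folds, "pet_folds"))
  check_column(data, "id", "data")
  check_column(data, "label", "data")
  fold_of <- folds$fold[match(as.character(data$id), folds$id)]
  if (any(is.na(fold_of))) abort("Fold assignment does not cover the data")

  fold_ids <- sort(unique(folds$fold))
  per_fold <- map(fold_ids, function(f) {
    train <- data[fold_of != f, , drop = FALSE]
    test <- data[fold_of == f, , drop = FALSE]
    model <- method$fit(train)
    pred <- method$predict(model, test)
    stopifnot(nrow(pred) == nrow(test))
    flagged <- !any(as_binary_label(test$label) == 1)
    m <- withCallingHandlers(
      compute_metrics(test$label, pred$label, pred$probability),
      warning = function(w) invokeRestart("muffleWarning")
    )
    add_column(m, fold = f, .before = 1) %>% mutate(flagged = flagged)
  })
  fold_metrics <- bind_rows(per_fold)
  if (any(fold_metrics$flagged)) {
    warn(sprintf("%d fold(s) without positive examples flagged",
                 sum(fold_metrics$flagged)))
  }
  structure(
    list(method = method$name %||% "method",
         fold_metrics = fold_metrics,
         means = dplyr::summarise(fold_metrics,
                                  dplyr::across(dplyr::all_of(METRIC_NAMES),
                                                mean)),
         folds = folds),
    class = "pet_cv"
  )
}

#' @exportS3Method base::print
print.pet_cv <- function(x, ...) {
  cat(sprintf("<pet_cv> method '%s', %d folds\n", x$method,
              nrow(x$fold_metrics)))
  cat("  means: ",
      paste(sprintf("%s %.3f", names(x$means), as.numeric(x$means[1, ])),
            collapse = "  "), "\n")
  invisible(x)
}

#' One-tail paired t-test on per-fold scores
#'
#' Tests whether the fold-paired mean difference `a - b` is positive (or
#' negative, per `direction`): `t = mean(d) / (sd(d) / sqrt(k))` with sample
#' standard deviation and `k - 1` degrees of freedom; the p-value is the
#' upper tail of Student's t. Degenerate zero-variance differences are
#' flagged: p = 0 when the mean difference favours the hypothesis direction,
#' p = 1 against it, p = 0.5 when the mean is also zero.
#'
#' @param a,b Equal-length (>= 2) fold-aligned score vectors.
#' @param direction `"a_greater"` (default) or `"b_greater"`.
#' @return A `pet_ttest` list: `t_stat`, `df`, `p_one_tail`, `direction`,
#'   `flag`.
#' @export
#' @examples
#' paired_ttest_one_tail(c(2, 3, 4), c(1, 1, 1))
paired_ttest_one_tail <- function(a, b, direction = c("a_greater", "b_greater")) {
  direction <- match.arg(direction)
  if (length(a) != length(b)) abort("Score vectors must have equal length")
  if (length(a) < 2) abort("Need at least two paired folds")
  d <- if (direction == "a_greater") a - b else b - a
  k <- length(d)
  s <- sd(d)
  flag <- NA_character_
  if (s == 0) {
    flag <- "zero-variance differences"
    p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t_stat <- mean(d) / (s / sqrt(k))
    p <- pt(t_stat, df = k - 1, lower.tail = FALSE)
  }
  structure(list(t_stat = t_stat, df = k - 1L, p_one_tail = p,
                 direction = direction, flag = flag),
            class = "pet_ttest")
}

#' @exportS3Method base::print
print.pet_ttest <- function(x, ...) {
  cat(sprintf("<pet_ttest> t = %.4f, df = %d, one-tail p = %.4g (%s)%s\n",
              x$t_stat, x$df, x$p_one_tail, x$direction,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Compare methods against a reference by one-tail paired t-tests
#'
#' For every non-reference method and each of the five performance measures,
#' tests the hypothesis that the reference method's per-fold scores exceed
#' the other method's, producing the familiar grid of p-values (methods as
#' rows, measures as columns). All methods must have been cross-validated on
#' the same fold assignment.
#'
#' @param results A named list of `pet_cv` objects (names are method names),
#'   or a single `pet_cv` when comparing a method to itself.
#' @param reference Name of the reference method within `results`.
#' @return A tibble with one row per non-reference method (or the reference
#'   itself if it is the only entry) and one p-value column per measure.
#' @export
compare_methods <- function(results, reference) {
  stopifnot(is.list(results), reference %in% names(results))
  ref <- results[[reference]]
  k_ref <- nrow(ref$fold_metrics)
  others <- names(results)
  if (length(others) > 1) others <- setdiff(others, reference)

  rows <- map(others, function(nm) {
    cv <- results[[nm]]
    if (nrow(cv$fold_metrics) != k_ref) {
      abort("All methods must share the same number of folds")
    }
    if (!identical(cv$folds$fold[order(cv$folds$id)],
                   ref$folds$fold[order(ref$folds$id)])) {
      abort("All methods must share the same fold assignment")
    }
    ps <- map_dbl(METRIC_NAMES, function(m) {
      paired_ttest_one_tail(ref$fold_metrics[[m]],
                            cv$fold_metrics[[m]])$p_one_tail
    })
    as_tibble(c(list(classifier = nm), setNames(as.list(ps), METRIC_NAMES)))
  })
  bind_rows(rows)
}

#' Summarise cross-validation results in a performance table
#'
#' One row per method with the mean of each per-fold measure — the familiar
#' classifier-comparison layout.
#'
#' @param results A named list of `pet_cv` objects.
#' @return A tibble with columns `classifier` and the five measures.
#' @export
performance_table <- function(results) {
  bind_rows(imap(results, function(cv, nm) {
    add_column(cv$means, classifier = nm, .before = 1)
  }))
}
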