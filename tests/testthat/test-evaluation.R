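test_that("k-fold splits partition the ids into near-equal folds", {
  f <- kfold_split(1:100, k = 10, seed = 3)
  expect_equal(sort(as.integer(f$id)), 1:100)
  expect_equal(unname(table(f$fold)), rep(10L, 10), ignore_attr = TRUE)

  f2 <- kfold_split(1:23, k = 5, seed = 3)
  sizes <- table(f2$fold)
  expect_lte(diff(range(sizes)), 1)
  # deterministic under the same seed
  expect_identical(kfold_split(1:23, k = 5, seed = 3), f2)
  expect_false(identical(kfold_split(1:23, k = 5, seed = 4)$fold, f2$fold))
  expect_error(kfold_split(1:5, k = 10), "exceeds")
  expect_error(kfold_split(1:5, k = 1), "at least 2")
})

test_that("stratified folds balance class counts within one example", {
  y <- rep(c("PET", "nonPET"), c(23, 77))
  f <- kfold_split(1:100, k = 10, seed = 1, stratify_labels = y)
  per_fold_pos <- table(f$fold[match(1:100, as.integer(f$id))[y == "PET"]])
  expect_lte(diff(range(per_fold_pos)), 1)
  expect_lte(diff(range(table(f$fold))), 1)
})

test_that("metrics match the confusion-matrix closed form", {
  # TP=3, FP=1, FN=2, TN=4
  y_true <- c(rep(1, 5), rep(0, 5))
  y_pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision_pet, 0.75)
  expect_equal(m$recall_pet, 0.6)
  expect_equal(m$f1_pet, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
})

test_that("undefined precision/recall is reported as zero with a warning", {
  expect_warning(m <- compute_metrics(c(1, 0), c(0, 0)), "Precision")
  expect_equal(m$precision_pet, 0)
  expect_equal(m$f1_pet, 0)
})

test_that("AUC: separation, ranking formulation vs brute force, invariance", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0), c(0.5, 0.5)), 0.5)  # tie counts half

  set.seed(10)
  for (i in 1:200) {
    n <- sample(5:500, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    score <- sample(round(runif(n), sample(1:3, 1)))  # induce ties
    expect_equal(roc_auc(y, score), brute_force_auc(y, score),
                 tolerance = 1e-12)
  }

  # order invariance
  y <- rbinom(50, 1, 0.4); s <- runif(50)
  perm <- sample(50)
  expect_equal(roc_auc(y[perm], s[perm]), roc_auc(y, s))
  # cross-check against an established ROC implementation
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(
                 y, s, levels = c(0, 1), direction = "<", quiet = TRUE
               ))),
               tolerance = 1e-12)
  expect_warning(a <- roc_auc(rep(1, 4), runif(4)), "one class")
  expect_true(is.na(a))
})

test_that("cross-validation reproduces the constant-classifier closed form", {
  # all-nonPET predictions on a 30%-PET dataset: accuracy 0.70, recall 0
  n <- 200
  data <- tibble::tibble(
    id = as.character(1:n),
    label = rep(c("PET", "nonPET"), c(60, 140)),
    x = rnorm(n)
  )
  folds <- kfold_split(data$id, k = 10, seed = 2,
                       stratify_labels = data$label)
  constant <- list(
    name = "always_negative",
    fit = function(train) NULL,
    predict = function(model, test) {
      tibble::tibble(probability = rep(0.1, nrow(test)),
                     label = rep("nonPET", nrow(test)))
    }
  )
  cv <- suppressWarnings(cross_validate(data, folds, constant))
  expect_equal(nrow(cv$fold_metrics), 10)
  expect_equal(cv$means$accuracy, 0.70, tolerance = 1e-12)
  expect_equal(cv$means$recall_pet, 0)
  # reported means equal the mean of per-fold metrics exactly
  expect_equal(cv$means$accuracy, mean(cv$fold_metrics$accuracy),
               tolerance = 1e-15)
})

test_that("paired one-tail t-test matches the df=2 analytic CDF", {
  r <- paired_ttest_one_tail(c(2, 3, 4), c(1, 1, 1))  # d = (1, 2, 3)
  expect_equal(r$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2L)
  # closed-form upper tail for df = 2: 1 - (1/2 + t / (2 sqrt(2 + t^2)))
  t <- r$t_stat
  expect_equal(r$p_one_tail, 1 - (0.5 + t / (2 * sqrt(2 + t^2))),
               tolerance = 1e-10)
  expect_equal(r$p_one_tail, 0.0371, tolerance = 1e-3)

  same <- paired_ttest_one_tail(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_one_tail, 0.5)
  expect_false(is.na(same$flag))

  # reversing direction complements the p-value
  a <- c(1.2, 1.5, 1.1, 1.9); b <- c(1.0, 1.6, 1.0, 1.4)
  p1 <- paired_ttest_one_tail(a, b)$p_one_tail
  p2 <- paired_ttest_one_tail(a, b, direction = "b_greater")$p_one_tail
  expect_equal(p1 + p2, 1, tolerance = 1e-12)

  expect_error(paired_ttest_one_tail(1:3, 1:4), "equal length")
  zv <- paired_ttest_one_tail(c(2, 2), c(1, 1))
  expect_equal(zv$p_one_tail, 0)
  expect_false(is.na(zv$flag))
})

test_that("compare_methods emits the comparison grid with self-p of 0.5", {
  n <- 120
  data <- tibble::tibble(id = as.character(1:n),
                         label = rep(c("PET", "nonPET"), c(40, 80)),
                         f = c(rnorm(40, 1), rnorm(80)))
  folds <- kfold_split(data$id, k = 6, seed = 5,
                       stratify_labels = data$label)
  lr <- cross_validate(data, folds, feature_table_method("logreg"))
  tree <- suppressWarnings(
    cross_validate(data, folds, feature_table_method("tree"))
  )

  self <- compare_methods(list(lr = lr), reference = "lr")
  expect_equal(as.numeric(self[1, -1]), rep(0.5, 5))

  grid <- compare_methods(list(lr = lr, tree = tree), reference = "lr")
  expect_equal(dim(grid), c(1, 6))
  expect_equal(grid$classifier, "tree")
  expect_true(all(names(grid)[-1] ==
                    c("accuracy", "precision_pet", "recall_pet", "f1_pet",
                      "roc_auc")))

  # mismatched folds are rejected
  other <- kfold_split(data$id, k = 6, seed = 99,
                       stratify_labels = data$label)
  tree2 <- suppressWarnings(
    cross_validate(data, other, feature_table_method("tree"))
  )
  expect_error(compare_methods(list(lr = lr, tree = tree2), reference = "lr"),
               "fold assignment")
})

test_that("a consistently better reference yields small p-values everywhere", {
  set.seed(11)
  k <- 10
  base <- runif(k, 0.6, 0.7)
  mk_cv <- function(scores, folds) {
    structure(list(
      method = "m",
      fold_metrics = tibble::tibble(
        fold = 0:(k - 1), accuracy = scores, precision_pet = scores,
        recall_pet = scores, f1_pet = scores, roc_auc = scores,
        flagged = FALSE
      ),
      means = NULL, folds = folds
    ), class = "pet_cv")
  }
  folds <- kfold_split(1:50, k = k, seed = 1)
  ref <- mk_cv(base + 0.1 + rnorm(k, sd = 1e-3), folds)
  weak <- mk_cv(base, folds)
  grid <- compare_methods(list(ref = ref, weak = weak), reference = "ref")
  expect_true(all(as.numeric(grid[1, -1]) < 0.01))
})
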