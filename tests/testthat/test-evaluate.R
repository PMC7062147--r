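test_that("absolute error is the signed elementwise difference", {
  expect_equal(absolute_error(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(absolute_error(c(10, 20), c(8, 25)), c(2, -5))
  expect_error(absolute_error(1:3, 1:2), "equal length")
})

test_that("normalized MAE matches hand computation and is affine-invariant", {
  expect_equal(mae_percent(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae_percent(c(0, 100), c(10, 90)), 10)
  expect_equal(mae_percent(c(0, 100), c(10, 90), "none"), 10)
  expect_error(mae_percent(c(5, 5, 5), c(1, 2, 3)), "zero range")
  set.seed(20)
  aj <- runif(50, 0, 90)
  pj <- aj + rnorm(50, sd = 4)
  base <- mae_percent(aj, pj)
  for (alpha in c(2.5, -1.3, 0.01)) {
    beta <- rnorm(1, sd = 10)
    expect_equal(mae_percent(alpha * aj + beta, alpha * pj + beta), base)
  }
})

test_that("classification metrics reproduce the defining counts", {
  y <- rep(c(0, 1), each = 10)
  p <- c(rep(0, 9), 1, 0, rep(1, 9))     # TP=9 FP=1 FN=1 TN=9 for class 0
  m <- classification_metrics(y, p, positive_class = 0)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  expect_equal(m$accuracy, 90)

  perfect <- classification_metrics(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(perfect$macro$precision, 1)
  expect_equal(perfect$macro$recall, 1)
  expect_equal(perfect$macro$f1, 1)
  expect_equal(perfect$accuracy, 100)

  wrong <- classification_metrics(c(0, 1, 2), c(1, 2, 0))
  expect_equal(wrong$accuracy, 0)

  expect_warning(m2 <- classification_metrics(c(0, 0, 1), c(0, 2, 1)),
                 "absent")
  expect_true(is.na(m2$per_class$recall[3]))
})

test_that("metrics match a brute-force counting oracle exactly", {
  set.seed(30)
  reps <- c(rep(50, 19), 1000)
  for (n in reps) {
    y <- sample(0:2, n, replace = TRUE)
    p <- sample(0:2, n, replace = TRUE)
    got <- suppressWarnings(classification_metrics(y, p))
    cm <- suppressWarnings(confusion_matrix(y, p))
    for (cl in 0:2) {
      tp <- fp <- fn <- tn <- 0
      for (i in seq_len(n)) {          # independent brute-force loop
        if (y[i] == cl && p[i] == cl) tp <- tp + 1
        else if (y[i] != cl && p[i] == cl) fp <- fp + 1
        else if (y[i] == cl && p[i] != cl) fn <- fn + 1
        else tn <- tn + 1
      }
      row <- got$per_class[got$per_class$class == cl, ]
      expect_identical(row$precision, if (tp + fp == 0) NA_real_ else tp / (tp + fp))
      expect_identical(row$recall, if (tp + fn == 0) NA_real_ else tp / (tp + fn))
      expect_identical(row$binary_accuracy, (tp + tn) / n * 100)
      if (tp + fn > 0) {
        for (cl2 in 0:2) {
          cnt <- sum(y == cl & p == cl2)
          expect_identical(cm[cl + 1, cl2 + 1], cnt / (tp + fn) * 100)
        }
      }
    }
    expect_identical(got$accuracy, sum(y == p) / n * 100)
  }
})

test_that("confusion matrix rows are percentages summing to 100", {
  cm <- confusion_matrix(c(0, 1, 2, 1), c(0, 1, 2, 0))
  expect_equal(unname(rowSums(cm)), c(100, 100, 100))
  expect_equal(diag(confusion_matrix(0:2, 0:2)), c(100, 100, 100),
               ignore_attr = TRUE)
  # uniform random predictions approach 33.3 per cell
  set.seed(31)
  y <- rep(0:2, each = 10000)
  p <- sample(0:2, 30000, replace = TRUE)
  cmr <- confusion_matrix(y, p)
  expect_true(all(abs(cmr - 100 / 3) < 4 * sqrt((1 / 3) * (2 / 3) / 10000) * 100))
  expect_warning(cme <- confusion_matrix(c(0, 0, 1), c(0, 1, 1)), "absent")
  expect_true(all(is.na(cme[3, ])))
})

test_that("pearson correlation behaves as expected", {
  a <- rnorm(100)
  expect_equal(pearson_corr(a, a), 1)
  expect_equal(pearson_corr(a, -a), -1)
  expect_equal(pearson_corr(a, a + 5), 1)
  expect_error(pearson_corr(a, a[-1]), "equal length")
})

test_that("fold aggregation reports mean and sample sd", {
  r1 <- metrics_report(mae_percent = 8, accuracy = 90, pearson_r = 0.99)
  r2 <- metrics_report(mae_percent = 10, accuracy = 100, pearson_r = 0.97)
  agg <- aggregate_folds(list(r1, r2))
  expect_equal(agg$accuracy, 95)
  expect_equal(agg$accuracy_sd, sd(c(90, 100)))  # 7.0710678
  expect_equal(agg$mae_percent, 9)
  expect_length(agg$folds, 2)
  same <- aggregate_folds(list(r1, r1, r1))
  expect_equal(same$accuracy, 90)
  expect_equal(same$accuracy_sd, 0)
  expect_warning(one <- aggregate_folds(list(r1)), "single fold")
  expect_equal(one$accuracy_sd, 0)
})

test_that("aggregated confusion matrices are re-normalized", {
  cm1 <- matrix(c(100, 0, 0, 0, 100, 0, 0, 0, 100), 3, 3, byrow = TRUE)
  cm2 <- matrix(c(80, 20, 0, 10, 90, 0, 0, 0, 100), 3, 3, byrow = TRUE)
  r1 <- metrics_report(accuracy = 100, confusion = cm1)
  r2 <- metrics_report(accuracy = 90, confusion = cm2)
  agg <- aggregate_folds(list(r1, r2))
  expect_equal(unname(rowSums(agg$confusion)), c(100, 100, 100))
  expect_equal(agg$confusion[1, 1], 90)
})
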