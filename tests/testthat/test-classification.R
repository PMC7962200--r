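test_that("metrics reproduce direct confusion-table arithmetic", {
  m <- classification_metrics(40, 45, 5, 10)
  expect_equal(unname(m), c(85, 80, 90, 800 / 9))
  # degenerate: no positives anywhere
  m0 <- classification_metrics(0, 12, 0, 0)
  expect_equal(m0[["acc"]], 100)
  expect_true(is.na(m0[["sen"]]))
  expect_equal(m0[["spe"]], 100)
  expect_true(is.na(m0[["pre"]]))
  expect_error(classification_metrics(-1, 2, 3, 4), "nonnegative")
  set.seed(41)
  for (trial in 1:25) {
    cnt <- sample(0:60, 4, replace = TRUE)
    if (sum(cnt) == 0) next
    m <- classification_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(m[["acc"]], (cnt[1] + cnt[2]) / sum(cnt) * 100)
    expect_equal(m[["acc"]], 100 - (cnt[3] + cnt[4]) / sum(cnt) * 100)
    if (cnt[1] + cnt[4] > 0)
      expect_equal(m[["sen"]], cnt[1] / (cnt[1] + cnt[4]) * 100)
    if (cnt[1] + cnt[3] > 0)
      expect_equal(m[["pre"]], cnt[1] / (cnt[1] + cnt[3]) * 100)
  }
})

make_blobs <- function(n_per_class, sep = 4, p = 2) {
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = sep), ncol = p))
  y <- factor(rep(c("low", "high"), each = n_per_class),
              levels = c("low", "high"))
  list(x = x, y = y)
}

test_that("the RBF support vector machine separates distant blobs", {
  set.seed(42)
  b <- make_blobs(40)
  pred <- svm_classifier(b$x, b$y, b$x)
  expect_equal(as.character(pred), as.character(b$y))
  expect_error(svm_classifier(b$x[1:40, ], b$y[1:40], b$x), "single class")
})

test_that("OF-KNN selects a small k on well-separated clusters, reproducibly", {
  set.seed(43)
  b <- make_blobs(30, sep = 6)
  pred <- ofknn_classifier(b$x, b$y, b$x, seed = 7)
  expect_equal(as.character(pred), as.character(b$y))
  expect_lte(attr(pred, "k"), 10)
  pred2 <- ofknn_classifier(b$x, b$y, b$x, seed = 7)
  expect_equal(attr(pred2, "k"), attr(pred, "k"))
  expect_equal(attr(pred2, "metric"), attr(pred, "metric"))
})

test_that("an optimization budget of one degenerates to the first candidate", {
  set.seed(44)
  b <- make_blobs(15)
  pred <- ofknn_classifier(b$x, b$y, b$x, optimization_budget = 1, seed = 1)
  expect_equal(attr(pred, "k"), 1L)
  expect_equal(attr(pred, "metric"), "euclidean")
})

test_that("neighbour counts are capped by the training-fold size", {
  set.seed(45)
  b <- make_blobs(6)  # 12 training rows; 5-fold leaves ~9 per fit
  pred <- ofknn_classifier(b$x, b$y, b$x, k_max = 50, seed = 2)
  expect_lte(attr(pred, "k"), 10)
})

test_that("the decision tree finds pure single splits and handles constants", {
  y <- factor(rep(c("low", "high"), each = 20), levels = c("low", "high"))
  x <- cbind(ifelse(y == "high", 1, 0) + rnorm(40, sd = 0.01), rnorm(40))
  pred <- dt_classifier(x, y, x)
  expect_equal(as.character(pred), as.character(y))
  # constant features: majority class everywhere
  xc <- matrix(1, 30, 3)
  yc <- factor(c(rep("low", 10), rep("high", 20)), levels = c("low", "high"))
  expect_true(all(dt_classifier(xc, yc, xc[1:5, , drop = FALSE]) == "high"))
})

test_that("a depth-one tree matches the exhaustive best stump", {
  set.seed(46)
  n <- 60
  x <- cbind(runif(n), runif(n))
  y <- factor(ifelse(x[, 1] + rnorm(n, sd = 0.15) > 0.5, "high", "low"),
              levels = c("low", "high"))
  stump_acc <- function() {
    best <- 0
    for (p in 1:2) for (thr in sort(unique(x[, p]))) {
      for (side in c(-1, 1)) {
        pred <- ifelse(side * (x[, p] - thr) > 0, "high", "low")
        best <- max(best, mean(pred == y))
      }
    }
    best
  }
  pred <- dt_classifier(x, y, x, max_depth = 1)
  expect_equal(mean(pred == y), stump_acc(), tolerance = 1e-12)
})

test_that("cross-validation folds cover all rows disjointly and reproducibly", {
  set.seed(47)
  b <- make_blobs(110)  # 220 rows
  rep1 <- cross_validate(b$x, b$y, 5, "dt", seed = 9)
  expect_equal(sort(unique(rep1$fold_assignment)), 1:5)
  expect_equal(length(rep1$fold_assignment), 220)
  expect_equal(sum(rep1$folds$n_test), 220)
  expect_equal(rep1$folds$tp + rep1$folds$tn + rep1$folds$fp +
                 rep1$folds$fn, rep1$folds$n_test)
  rep2 <- cross_validate(b$x, b$y, 5, "dt", seed = 9)
  expect_identical(rep1$folds, rep2$folds)
  expect_error(cross_validate(b$x, b$y, 500, "dt"), "exceeds")
})

test_that("440 stratified rows split 352/88 in five folds", {
  set.seed(48)
  y <- factor(rep(c("low", "high"), each = 220), levels = c("low", "high"))
  folds <- make_folds(y, 5, seed = 3)
  expect_true(all(table(folds) == 88))
  expect_true(all(table(folds, y) == 44))
})

test_that("a perfect classifier scores 100 everywhere with zero spread", {
  set.seed(49)
  y <- factor(rep(c("low", "high"), 30), levels = c("low", "high"))
  x <- cbind(as.numeric(y), rnorm(60))
  perfect <- function(train_x, train_y, test_x)
    factor(ifelse(test_x[, 1] > 1.5, "high", "low"),
           levels = c("low", "high"))
  rep <- cross_validate(x, y, 5, perfect, seed = 1)
  expect_equal(unname(rep$mean), rep(100, 4))
  expect_equal(unname(rep$sd), rep(0, 4))
})

test_that("label permutation drives accuracy to chance", {
  set.seed(50)
  b <- make_blobs(60, sep = 5)
  y_perm <- sample(b$y)
  rep <- cross_validate(b$x, y_perm, 5, "dt", seed = 13)
  expect_gt(rep$mean[["acc"]], 30)
  expect_lt(rep$mean[["acc"]], 70)
})

test_that("grouped folds keep all rows of a trial together", {
  set.seed(51)
  groups <- rep(1:20, each = 11)
  y <- factor(rep(rep(c("low", "high"), 10), each = 11),
              levels = c("low", "high"))
  folds <- make_folds(y, 5, seed = 2, groups = groups)
  expect_true(all(tapply(folds, groups, function(f) length(unique(f))) == 1))
})

test_that("report aggregation averages per-report means", {
  set.seed(52)
  b <- make_blobs(40)
  r1 <- cross_validate(b$x, b$y, 5, "dt", seed = 1)
  r2 <- cross_validate(b$x, b$y, 10, "dt", seed = 1)
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(agg$mean[["acc"]], mean(c(r1$mean[["acc"]], r2$mean[["acc"]])))
})
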