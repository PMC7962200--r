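#' Binary classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity and precision, each as a
#' percentage:
#' Acc = (TP+TN)/(TP+TN+FP+FN), Sen = TP/(TP+FN), Spe = TN/(TN+FP),
#' Pre = TP/(TP+FP), all x 100. A metric whose denominator is zero is
#' undefined and reported as `NA`.
#'
#' @param tp,tn,fp,fn nonnegative counts of true positives, true negatives,
#'   false positives and false negatives.
#' @return named numeric vector `acc`, `sen`, `spe`, `pre` in percent.
#' @examples
#' classification_metrics(40, 45, 5, 10)
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  total <- tp + tn + fp + fn
  ratio <- function(num, den) if (den > 0) num / den * 100 else NA_real_
  c(acc = ratio(tp + tn, total),
    sen = ratio(tp, tp + fn),
    spe = ratio(tn, tn + fp),
    pre = ratio(tp, tp + fp))
}

confusion_counts <- function(pred, truth, positive) {
  pred <- as.character(pred); truth <- as.character(truth)
  c(tp = sum(pred == positive & truth == positive),
    tn = sum(pred != positive & truth != positive),
    fp = sum(pred == positive & truth != positive),
    fn = sum(pred != positive & truth == positive))
}

check_training_set <- function(train_x, train_y) {
  if (nrow(train_x) != length(train_y))
    stop("training rows and labels differ in length")
  if (nlevels(droplevels(factor(train_y))) < 2L)
    stop("training set contains a single class; cannot fit a classifier")
}

#' RBF support vector machine classifier
#'
#' Soft-margin C-classification SVM with a radial basis kernel; the defaults
#' are penalty `cost = 2` and kernel width `gamma = 1`. Features arrive
#' min-max normalized from the pipeline, so no internal rescaling is done.
#'
#' @param train_x,train_y training matrix and factor labels.
#' @param test_x matrix of rows to predict.
#' @param cost soft-margin penalty C.
#' @param gamma RBF kernel width.
#' @return factor of predicted labels for `test_x`.
#' @export
svm_classifier <- function(train_x, train_y, test_x, cost = 2, gamma = 1) {
  train_y <- factor(train_y)
  check_training_set(train_x, train_y)
  fit <- e1071::svm(train_x, train_y, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  stats::predict(fit, test_x)
}

cross_distances <- function(a, b, metric) {
  switch(metric,
    euclidean = {
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      sqrt(pmax(d2, 0))
    },
    cityblock = {
      d <- matrix(0, nrow(a), nrow(b))
      for (p in seq_len(ncol(a)))
        d <- d + abs(outer(a[, p], b[, p], "-"))
      d
    },
    cosine = {
      na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
      na[na == 0] <- .Machine$double.eps
      nb[nb == 0] <- .Machine$double.eps
      1 - tcrossprod(a / na, b / nb)
    },
    stop("unknown distance metric: ", metric))
}

knn_vote <- function(ordered_classes, k, n_levels) {
  counts <- tabulate(ordered_classes[seq_len(k)], nbins = n_levels)
  winners <- which(counts == max(counts))
  if (length(winners) == 1L) return(winners)
  # tie: side with the class of the nearest neighbour if it is tied, else
  # with the tied class appearing earliest in the neighbour list
  nearest <- ordered_classes[1L]
  if (nearest %in% winners) return(nearest)
  winners[which.min(vapply(winners, function(w)
    match(w, ordered_classes[seq_len(k)]), integer(1)))]
}

knn_predict_ordered <- function(d, train_y, k) {
  nl <- nlevels(train_y)
  pred <- integer(nrow(d))
  for (r in seq_len(nrow(d))) {
    ord <- order(d[r, ])
    pred[r] <- knn_vote(as.integer(train_y)[ord], min(k, ncol(d)), nl)
  }
  factor(levels(train_y)[pred], levels = levels(train_y))
}

#' Optimized k-nearest-neighbour classifier (OF-KNN)
#'
#' k-nearest neighbours whose neighbour count k and distance metric
#' (Euclidean, cityblock, cosine) are selected to minimize 5-fold
#' cross-validation loss on the training partition, by exhaustive
#' enumeration of the candidate grid; the best configuration is refit on
#' the full training set and applied to the test rows. Exhaustive scanning
#' of a grid this small finds the same optimum a Bayesian search would,
#' deterministically. Ties in CV loss go to the earliest candidate
#' (metrics in the order given, then smaller k).
#'
#' @inheritParams svm_classifier
#' @param k_max largest neighbour count tried (capped at the training-fold
#'   size).
#' @param metrics distance metrics to try.
#' @param cv_folds folds of the internal loss estimate.
#' @param optimization_budget maximum number of (metric, k) candidates
#'   evaluated, scanned in grid order; a budget of 1 degenerates to the
#'   first candidate (Euclidean, k = 1).
#' @param seed seed for the internal fold split.
#' @return factor of predicted labels for `test_x`, with the chosen
#'   configuration in attributes `k` and `metric`.
#' @export
ofknn_classifier <- function(train_x, train_y, test_x, k_max = 30,
                             metrics = c("euclidean", "cityblock", "cosine"),
                             cv_folds = 5, optimization_budget = Inf,
                             seed = NULL) {
  train_y <- factor(train_y)
  check_training_set(train_x, train_y)
  n <- nrow(train_x)
  folds <- make_folds(train_y, min(cv_folds, n), seed = seed,
                      stratified = TRUE)
  k_cap <- min(k_max, min(vapply(seq_len(max(folds)), function(f)
    sum(folds != f), integer(1))))
  grid <- expand.grid(k = seq_len(k_cap), metric = metrics,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$metric, metrics), grid$k), ]
  if (is.finite(optimization_budget))
    grid <- grid[seq_len(max(1, min(nrow(grid), optimization_budget))), ]

  losses <- rep(NA_real_, nrow(grid))
  for (m in unique(grid$metric)) {
    rows_m <- which(grid$metric == m)
    ks <- grid$k[rows_m]
    d_all <- cross_distances(train_x, train_x, m)
    errs <- matrix(0, max(folds), max(ks))
    for (f in seq_len(max(folds))) {
      val <- which(folds == f); trn <- which(folds != f)
      yt <- as.integer(train_y)[trn]
      for (v in val) {
        ord_classes <- yt[order(d_all[v, trn])]
        truth <- as.integer(train_y)[v]
        for (k in seq_len(max(ks))) {
          p <- knn_vote(ord_classes, min(k, length(trn)), nlevels(train_y))
          errs[f, k] <- errs[f, k] + (p != truth)
        }
      }
      errs[f, ] <- errs[f, ] / length(val)
    }
    losses[rows_m] <- colMeans(errs)[ks]
  }
  best <- which.min(losses)  # first minimum = earliest candidate
  k_best <- grid$k[best]; metric_best <- grid$metric[best]
  d_test <- cross_distances(test_x, train_x, metric_best)
  pred <- knn_predict_ordered(d_test, train_y, k_best)
  attr(pred, "k") <- k_best
  attr(pred, "metric") <- metric_best
  pred
}

#' CART decision-tree classifier
#'
#' Binary recursive partitioning on the Gini impurity (via `rpart`), grown
#' with `minsplit = 2` and pruned only by the complexity parameter, so a
#' perfectly separable single split is found at depth 1 and constant
#' features yield the majority class.
#'
#' @inheritParams svm_classifier
#' @param max_depth maximum tree depth.
#' @param cp complexity parameter of `rpart`.
#' @return factor of predicted labels for `test_x`.
#' @export
dt_classifier <- function(train_x, train_y, test_x, max_depth = 30,
                          cp = 0.01) {
  train_y <- factor(train_y)
  check_training_set(train_x, train_y)
  df <- as.data.frame(train_x)
  names(df) <- paste0("f", seq_len(ncol(train_x)))
  df$.y <- train_y
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = 2, maxdepth = max_depth, cp = cp,
                        xval = 0))
  nd <- as.data.frame(test_x)
  names(nd) <- paste0("f", seq_len(ncol(test_x)))
  stats::predict(fit, nd, type = "class")
}

#' Seeded (stratified) fold assignment
#'
#' @param y factor labels.
#' @param k number of folds.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param stratified balance class proportions across folds.
#' @param groups optional grouping vector (e.g. trial ids); all rows of a
#'   group land in the same fold.
#' @return integer vector of fold ids in 1..k, one per row.
#' @export
make_folds <- function(y, k, seed = NULL, stratified = TRUE, groups = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  if (k < 2L || k > n) stop("need 2 <= k <= number of rows")
  folds <- integer(n)
  if (!is.null(groups)) {
    ug <- unique(groups)
    gf <- rep(seq_len(k), length.out = length(ug))[sample.int(length(ug))]
    folds <- gf[match(groups, ug)]
  } else if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- rep(seq_len(k),
                        length.out = length(idx))[sample.int(length(idx))]
    }
  } else {
    folds <- rep(seq_len(k), length.out = n)[sample.int(n)]
  }
  folds
}

builtin_classifier <- function(name) {
  switch(name,
         svm = svm_classifier,
         ofknn = ofknn_classifier,
         dt = dt_classifier,
         stop("unknown classifier: ", name))
}

#' k-fold cross-validated evaluation
#'
#' Splits the rows into k seeded (stratified by default) folds, trains the
#' classifier on k-1 folds and evaluates on the held-out fold, and reports
#' per-fold confusion counts with accuracy, sensitivity, specificity and
#' precision plus their mean and standard deviation across folds. The
#' positive class for sensitivity/precision is `"high"` when present.
#'
#' Rows are assigned to folds independently by default, mirroring
#' segment-level evaluation; pass `groups` (e.g. trial ids) to keep all
#' segments of a trial in one fold — overlapping segments of one trial
#' otherwise share samples across the train/test boundary.
#'
#' @param x samples x features matrix.
#' @param y factor labels.
#' @param k_folds number of folds (5 and 10 are the usual choices).
#' @param classifier `"svm"`, `"ofknn"`, `"dt"`, or a function
#'   `(train_x, train_y, test_x) -> factor`.
#' @param seed integer seed for the fold split.
#' @param stratified stratify folds by class.
#' @param groups optional grouping vector for grouped folds.
#' @param ... passed on to the classifier.
#' @return an `evaluation_report`: list with `folds` (per-fold data frame),
#'   `mean`, `sd`, and the fold assignment.
#' @export
cross_validate <- function(x, y, k_folds = 5, classifier = "svm", seed = 1,
                           stratified = TRUE, groups = NULL, ...) {
  x <- as.matrix(x); y <- factor(y)
  if (nrow(x) != length(y)) stop("rows of x and length of y differ")
  if (k_folds > nrow(x))
    stop("k_folds (", k_folds, ") exceeds the number of rows (", nrow(x), ")")
  clf <- if (is.function(classifier)) classifier
         else builtin_classifier(match.arg(classifier,
                                           c("svm", "ofknn", "dt")))
  positive <- if ("high" %in% levels(y)) "high" else levels(y)[nlevels(y)]
  folds <- make_folds(y, k_folds, seed = seed, stratified = stratified,
                      groups = groups)
  res <- lapply(seq_len(k_folds), function(f) {
    te <- which(folds == f); tr <- which(folds != f)
    pred <- clf(x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE], ...)
    cc <- confusion_counts(pred, y[te], positive)
    c(fold = f, n_test = length(te), cc, classification_metrics(
      cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]]))
  })
  df <- as.data.frame(do.call(rbind, res))
  metric_cols <- c("acc", "sen", "spe", "pre")
  structure(list(folds = df,
                 mean = colMeans(df[metric_cols], na.rm = TRUE),
                 sd = apply(df[metric_cols], 2, stats::sd, na.rm = TRUE),
                 positive = positive,
                 fold_assignment = folds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d folds, positive class '%s'\n",
              nrow(x$folds), x$positive))
  for (m in c("acc", "sen", "spe", "pre"))
    cat(sprintf("  %-4s mean %6.2f%%  STD %5.2f\n",
                toupper(m), x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Aggregate evaluation reports across subjects or repeats
#'
#' Averages the per-report mean metrics (e.g. the 5-fold and 10-fold runs
#' of one subject, or the per-subject results of a cohort) and reports the
#' across-report mean and standard deviation of each metric.
#'
#' @param reports list of `evaluation_report`s.
#' @return list with `mean` and `sd` named vectors over acc/sen/spe/pre.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) > 0,
            all(vapply(reports, inherits, logical(1), "evaluation_report")))
  m <- do.call(rbind, lapply(reports, `[[`, "mean"))
  list(mean = colMeans(m), sd = apply(m, 2, stats::sd))
}
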