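# Confusion counts, classification metrics, stratified cross-validation.

#' Confusion counts
#'
#' K x K confusion matrix (rows = truth, columns = prediction) together
#' with the per-class one-vs-rest true/false positive/negative counts.
#'
#' @param y_true,y_pred equal-length label vectors: factors sharing levels,
#'   or integers in 0..K-1.
#' @param k number of classes; inferred from factor levels when omitted.
#' @return an object of class `confusion_counts`: list with `matrix`,
#'   `classes`, and per-class vectors `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, k = NULL) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (is.factor(y_true) || is.factor(y_pred)) {
    lev <- levels(as.factor(y_true))
    if (is.null(k)) k <- length(lev)
    ti <- as.integer(factor(y_true, levels = lev))
    pi_ <- as.integer(factor(y_pred, levels = lev))
    classes <- lev
  } else {
    if (is.null(k)) k <- max(c(y_true, y_pred, -1)) + 1L
    if (length(y_true) > 0 &&
        (any(y_true < 0 | y_true >= k) || any(y_pred < 0 | y_pred >= k)))
      stop("labels out of range 0..K-1")
    ti <- as.integer(y_true) + 1L
    pi_ <- as.integer(y_pred) + 1L
    classes <- as.character(0:(k - 1L))
  }
  if (any(is.na(ti)) || any(is.na(pi_))) stop("prediction labels outside truth levels")
  m <- matrix(tabulate((ti - 1L) * k + pi_, k * k), k, k, byrow = TRUE,
              dimnames = list(truth = classes, predicted = classes))
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- sum(m) - tp - fp - fn
  structure(list(matrix = m, classes = classes, tp = tp, tn = tn,
                 fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Overall accuracy, per-class one-vs-rest precision/recall/F1 (harmonic
#' mean), their unweighted macro means, and pooled micro precision/recall.
#' For single-label multiclass problems the pooled micro recall (and micro
#' precision) equals the overall accuracy. Classes with a zero denominator
#' yield 0 with a warning.
#'
#' @param cc a `confusion_counts` object.
#' @return a list of class `metric_report` with elements `accuracy`,
#'   `per_class` (data.frame), `macro` and `micro` (named vectors).
#' @export
classification_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  n <- sum(cc$matrix)
  if (n == 0) stop("confusion counts are empty")
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning("zero denominator in ", what, " for class(es) ",
              paste(cc$classes[den == 0], collapse = ", "), "; reported as 0")
    out
  }
  prec <- safe_div(cc$tp, cc$tp + cc$fp, "precision")
  rec <- safe_div(cc$tp, cc$tp + cc$fn, "recall")
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class_acc <- (cc$tp + cc$tn) / n
  micro_prec <- sum(cc$tp) / sum(cc$tp + cc$fp)
  micro_rec <- sum(cc$tp) / sum(cc$tp + cc$fn)
  structure(list(
    accuracy = sum(cc$tp) / n,
    per_class = data.frame(class = cc$classes, precision = prec, recall = rec,
                           f1 = f1, accuracy = per_class_acc,
                           row.names = NULL),
    macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    micro = c(precision = micro_prec, recall = micro_rec)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f | micro P %.4f R %.4f\n",
              x$accuracy, x$macro["precision"], x$macro["recall"],
              x$macro["f1"], x$micro["precision"], x$micro["recall"]))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Stratified cross-validation folds
#'
#' Partitions sample indices into k folds preserving class proportions.
#'
#' @param labels factor of class labels.
#' @param k number of folds (>= 2); every class must have at least k
#'   members.
#' @param seed seed for the within-class shuffling.
#' @return a list of k index vectors forming a partition.
#' @export
cv_folds <- function(labels, k, seed = 1) {
  labels <- as.factor(labels)
  if (k < 2L) stop("k must be >= 2")
  cnt <- table(labels)
  if (any(cnt < k))
    stop("class(es) smaller than k: ", paste(names(cnt)[cnt < k], collapse = ", "))
  with_seed(seed, function() {
    folds <- vector("list", k)
    for (ix in split(seq_along(labels), labels)) {
      ix <- sample(ix)
      fid <- rep_len(seq_len(k), length(ix))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], ix[fid == f])
    }
    lapply(folds, sort)
  })
}

#' k-fold cross-validation of a classifier
#'
#' Runs stratified k-fold cross-validation: `fit_predict(train_idx,
#' test_idx)` must return predicted labels for the test indices. Reports
#' per-fold accuracy, their mean, sample standard deviation, and the
#' normal-approximation 95% confidence interval `mean +/- 1.96 * sd /
#' sqrt(k)`.
#'
#' @param labels factor of true labels for all samples.
#' @param fit_predict function of `(train_idx, test_idx)` returning
#'   predictions aligned with `test_idx`.
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @return a list of class `cv_summary` with `k`, `fold_scores`, `mean`,
#'   `sd`, `ci` (length-2 vector).
#' @export
cross_validate <- function(labels, fit_predict, k = 5, seed = 1) {
  labels <- as.factor(labels)
  folds <- cv_folds(labels, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    pred <- fit_predict(train_idx, test_idx)
    mean(as.character(pred) == as.character(labels[test_idx]))
  }, numeric(1))
  m <- mean(scores)
  s <- if (k > 1) sd(scores) else 0
  half <- 1.96 * s / sqrt(k)
  structure(list(k = k, fold_scores = scores, mean = m, sd = s,
                 ci = c(lower = m - half, upper = m + half)),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean accuracy %.4f, sd %.4f, 95%% CI [%.4f, %.4f]\n",
              x$k, x$mean, x$sd, x$ci[1], x$ci[2]))
  invisible(x)
}
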