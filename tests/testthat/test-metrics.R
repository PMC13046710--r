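test_that("confusion counts match exhaustive enumeration on the binary toy", {
  y_true <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0)
  cc <- confusion_counts(y_true, y_pred, k = 2)
  expect_equal(unname(cc$tp["1"]), 4)
  expect_equal(unname(cc$fn["1"]), 1)
  expect_equal(unname(cc$fp["1"]), 1)
  expect_equal(unname(cc$tn["1"]), 4)
  expect_equal(sum(cc$matrix), 10)
  m <- classification_metrics(cc)
  expect_equal(unname(m$per_class$precision[2]), 0.8)
  expect_equal(unname(m$per_class$recall[2]), 0.8)
  expect_equal(unname(m$per_class$f1[2]), 0.8)
  expect_equal(m$accuracy, 0.8)
})

test_that("perfect predictions give a diagonal matrix and unit metrics", {
  y <- factor(rep(letters[1:3], times = c(4, 3, 5)))
  cc <- confusion_counts(y, y)
  expect_equal(sum(cc$matrix) - sum(diag(cc$matrix)), 0)
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$macro), c(1, 1, 1))
  expect_equal(unname(m$micro), c(1, 1))
})

test_that("empty and invalid inputs are handled per contract", {
  cc <- confusion_counts(integer(0), integer(0), k = 3)
  expect_equal(cc$matrix, matrix(0L, 3, 3,
    dimnames = list(truth = as.character(0:2), predicted = as.character(0:2))))
  expect_error(classification_metrics(cc), "empty")
  expect_error(confusion_counts(c(0, 5), c(0, 1), k = 3), "range")
  expect_error(confusion_counts(0:1, 0L, k = 2), "length")
})

test_that("confusion counts are invariant to sample order", {
  set.seed(10)
  yt <- sample(0:3, 60, replace = TRUE)
  yp <- sample(0:3, 60, replace = TRUE)
  ord <- sample(60)
  expect_equal(confusion_counts(yt, yp, 4)$matrix,
               confusion_counts(yt[ord], yp[ord], 4)$matrix)
})

test_that("micro recall equals accuracy for single-label multiclass", {
  set.seed(3)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    yt <- sample(0:(k - 1), 80, replace = TRUE)
    yp <- sample(0:(k - 1), 80, replace = TRUE)
    m <- suppressWarnings(classification_metrics(confusion_counts(yt, yp, k)))
    expect_equal(unname(m$micro["recall"]), m$accuracy, tolerance = 1e-12)
    expect_equal(unname(m$micro["precision"]), m$accuracy, tolerance = 1e-12)
    expect_lte(unname(m$macro["f1"]), max(m$per_class$f1) + 1e-12)
    expect_gte(unname(m$macro["f1"]), min(m$per_class$f1) - 1e-12)
  }
})

test_that("zero-denominator classes report zero with a warning", {
  # class 2 never occurs and is never predicted
  cc <- confusion_counts(c(0, 0, 1, 1), c(0, 1, 1, 0), k = 3)
  expect_warning(m <- classification_metrics(cc), "zero denominator")
  expect_equal(m$per_class$f1[3], 0)
})

test_that("stratified folds partition the data and balance classes", {
  y <- factor(rep(c("a", "b", "c"), times = c(20, 15, 10)))
  folds <- cv_folds(y, k = 5, seed = 4)
  expect_equal(sort(unlist(folds)), 1:45)
  for (f in folds) {
    expect_equal(sum(y[f] == "a"), 4)
    expect_equal(sum(y[f] == "b"), 3)
    expect_equal(sum(y[f] == "c"), 2)
  }
  expect_error(cv_folds(factor(c("a", "a", "b")), k = 2), "smaller than k")
  expect_error(cv_folds(y, k = 1), "k must be")
})

test_that("cross-validation summarizes fold scores with the stated formulas", {
  y <- factor(rep(c("a", "b"), each = 10))
  # a classifier that is always right -> all folds score 1
  cv1 <- cross_validate(y, function(tr, te) y[te], k = 5, seed = 1)
  expect_equal(cv1$fold_scores, rep(1, 5))
  expect_equal(cv1$mean, 1)
  expect_equal(cv1$sd, 0)
  expect_equal(unname(cv1$ci), c(1, 1))
  # engineered fold scores {0.9, 1.0} at k = 2
  flip <- new.env(); flip$i <- 0
  cv2 <- cross_validate(y, function(tr, te) {
    flip$i <- flip$i + 1
    out <- as.character(y[te])
    if (flip$i == 1) out[1] <- setdiff(c("a", "b"), out[1])
    factor(out, levels = levels(y))
  }, k = 2, seed = 2)
  expect_equal(sort(cv2$fold_scores), c(0.9, 1.0))
  expect_equal(cv2$mean, 0.95)
  expect_equal(cv2$sd, sd(c(0.9, 1.0)), tolerance = 1e-12)
  expect_equal(unname(cv2$ci),
               0.95 + c(-1, 1) * 1.96 * sd(c(0.9, 1)) / sqrt(2),
               tolerance = 1e-12)
})
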