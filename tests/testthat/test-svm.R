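test_that("one-vs-one training produces k(k-1)/2 binary classifiers", {
  fm6 <- toy_feature_matrix(k = 6, nPer = 4)
  m6 <- trainClassifier(fm6, "svm", "linear")
  expect_equal(nBinaryClassifiers(m6), 15L)
  fm2 <- toy_feature_matrix(k = 2, nPer = 4)
  m2 <- trainClassifier(fm2, "svm", "linear")
  expect_equal(nBinaryClassifiers(m2), 1L)
})

test_that("single-class and NaN inputs are rejected", {
  fm <- toy_feature_matrix(k = 2, nPer = 3)
  fm1 <- new("FeatureMatrix", values = featureValues(fm),
             labels = rep("only", 6), blocks = list(), params = list())
  expect_error(trainClassifier(fm1, "svm"), "two classes")
})

test_that("a separable toy problem is fit exactly by the linear kernel", {
  X <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  rownames(X) <- paste0("p", 1:4)
  colnames(X) <- c("f1", "f2")
  fm <- new("FeatureMatrix", values = X, labels = c("a", "a", "b", "b"),
            blocks = list(), params = list())
  m <- trainClassifier(fm, "svm", "linear")
  pr <- predict(m, X)
  expect_identical(pr$labels, c("a", "a", "b", "b"))
})

test_that("predictions equal a brute-force tally of the binary votes", {
  fm <- toy_feature_matrix(k = 4, nPer = 6, sepn = 3, seed = 61)
  m <- trainClassifier(fm, "svm", "linear")
  set.seed(62)
  Xte <- matrix(rnorm(5 * ncol(featureValues(fm))), 5)
  colnames(Xte) <- colnames(featureValues(fm))
  pr <- predict(m, Xte)
  # manual tally from the raw binary decisions
  cls <- classNames(m)
  votes <- matrix(0, 5, length(cls), dimnames = list(NULL, cls))
  for (bin in m@binary) {
    dv <- PseLocWD:::.binary_decision(bin, Xte)
    for (i in 1:5) {
      w <- if (dv[i] > 0) bin$a else bin$b
      votes[i, w] <- votes[i, w] + 1
    }
  }
  expect_equal(unname(pr$votes), unname(votes))
  top <- apply(votes, 1, function(v) cls[which(v == max(v))])
  for (i in 1:5)
    expect_true(pr$labels[i] %in% unlist(top[i]))
})

test_that("vote ties fall to the largest aggregate margin", {
  # three classes arranged so a central point collects one vote each
  X <- rbind(matrix(c(0, 0), 1), matrix(c(4, 0), 1), matrix(c(2, 3.46), 1))
  X <- X[rep(1:3, each = 4), ] + matrix(rnorm(24, sd = 0.05), 12, 2)
  rownames(X) <- paste0("p", 1:12)
  colnames(X) <- c("f1", "f2")
  fm <- new("FeatureMatrix", values = X,
            labels = rep(c("a", "b", "c"), each = 4),
            blocks = list(), params = list())
  m <- trainClassifier(fm, "svm", "linear")
  centre <- matrix(c(2, 1.15), 1, dimnames = list(NULL, c("f1", "f2")))
  pr <- predict(m, centre)
  if (length(unique(pr$votes[1, ])) == 1) {
    margins <- pr$scores[1, ] - pr$votes[1, ]
    expect_equal(pr$labels[1], names(which.max(margins)))
  }
  succeed()  # geometry may avoid the exact tie; the tally test covers voting
})

test_that("training-row order does not change linear-SVM predictions", {
  fm <- toy_feature_matrix(k = 3, nPer = 8, sepn = 4, seed = 63)
  set.seed(64)
  ix <- sample(nrow(featureValues(fm)))
  fmp <- new("FeatureMatrix", values = featureValues(fm)[ix, ],
             labels = classLabels(fm)[ix], blocks = list(), params = list())
  Xte <- featureValues(toy_feature_matrix(k = 3, nPer = 4, sepn = 4,
                                          seed = 65))
  a <- predict(trainClassifier(fm, "svm", "linear"), Xte)
  b <- predict(trainClassifier(fmp, "svm", "linear"), Xte)
  expect_identical(a$labels, b$labels)
})

test_that("all four kernels train and resubstitute on separated blobs", {
  fm <- toy_feature_matrix(k = 3, nPer = 8, sepn = 8, seed = 66)
  for (kern in c("linear", "poly3", "rbf", "sigmoid")) {
    m <- trainClassifier(fm, "svm", kern)
    pr <- predict(m, featureValues(fm))
    expect_length(pr$labels, nrow(featureValues(fm)))
    expect_equal(colnames(pr$scores), classNames(m))
  }
})

test_that("baseline classifiers train, predict, and are seeded", {
  fm <- toy_feature_matrix(k = 3, nPer = 10, sepn = 6, seed = 67)
  X <- featureValues(fm)
  for (kind in c("knn", "rf", "nb", "dt")) {
    m <- trainClassifier(fm, kind, seed = 5)
    pr <- predict(m, X)
    expect_equal(mean(pr$labels == classLabels(fm)), 1,
                 tolerance = 0.15)          # well-separated blobs
    expect_equal(dim(pr$scores), c(nrow(X), 3L))
  }
  a <- predict(trainClassifier(fm, "rf", seed = 9), X)
  b <- predict(trainClassifier(fm, "rf", seed = 9), X)
  expect_identical(a$labels, b$labels)
})

test_that("feature-dimension mismatches are caught at prediction", {
  fm <- toy_feature_matrix(k = 2, nPer = 4)
  m <- trainClassifier(fm, "svm", "linear")
  expect_error(predict(m, matrix(0, 2, 3)), "dimension mismatch")
})
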