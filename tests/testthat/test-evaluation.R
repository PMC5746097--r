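test_that("a perfect confusion matrix yields unit metrics", {
  cm <- diag(c(10, 12, 8))
  dimnames(cm) <- list(c("a", "b", "c"), c("a", "b", "c"))
  met <- perClassMetrics(cm)
  expect_true(all(met$perClass$Sens == 1))
  expect_true(all(met$perClass$Spec == 1))
  expect_true(all(met$perClass$MCC == 1))
  expect_equal(met$oa, 1)
  expect_equal(met$mccMacro, 1)
})

test_that("binary-collapse metrics match hand evaluation", {
  # collapse with TP=8, FN=2, TN=85, FP=5
  cm <- matrix(c(8, 2, 5, 85), 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  met <- perClassMetrics(cm)
  oracle <- bf_metrics(tp = 8, fp = 5, tn = 85, fn = 2)
  expect_equal(met$perClass$Sens[1], 0.8)
  expect_equal(met$perClass$Spec[1], 85 / 90)
  expect_equal(met$perClass$MCC[1], oracle$mcc, tolerance = 1e-12)
  expect_equal(met$oa, 93 / 100)
})

test_that("metrics match brute force on random multiclass matrices", {
  set.seed(71)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    cm <- matrix(rpois(k * k, 5) + diag(k) * 20, k)
    dimnames(cm) <- list(paste0("c", 1:k), paste0("c", 1:k))
    met <- perClassMetrics(cm)
    n <- sum(cm)
    for (c in 1:k) {
      tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp
      fp <- sum(cm[, c]) - tp; tn <- n - tp - fn - fp
      o <- bf_metrics(tp, fp, tn, fn)
      expect_equal(met$perClass$Sens[c], o$sens, tolerance = 1e-12)
      expect_equal(met$perClass$Spec[c], o$spec, tolerance = 1e-12)
      expect_equal(met$perClass$MCC[c], o$mcc, tolerance = 1e-12)
    }
    expect_equal(met$oa, sum(diag(cm)) / n)
    # OA equals recall weighted by class sizes
    expect_equal(met$oa,
                 sum(met$perClass$Sens * rowSums(cm)) / n,
                 tolerance = 1e-12)
  }
})

test_that("degenerate MCC denominators give 0 with a warning", {
  cm <- matrix(c(5, 0, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  w <- capture_warnings(met <- perClassMetrics(cm))
  expect_match(w, "MCC denominator", all = TRUE)
  expect_equal(met$perClass$MCC[1], 0)   # both collapses are degenerate
  expect_equal(met$perClass$MCC[2], 0)
  expect_error(perClassMetrics(matrix(0, 2, 2)), "empty")
})

test_that("jackknife runs exactly n folds and is deterministic", {
  fm <- toy_feature_matrix(k = 2, nPer = 5, sepn = 5, seed = 72)
  r1 <- jackknife(fm, kind = "svm", kernel = "linear")
  expect_equal(sum(confusion(r1)), 10)
  expect_equal(r1@protocol, "jackknife")
  r2 <- jackknife(fm, kind = "svm", kernel = "linear")
  expect_identical(confusion(r1), confusion(r2))
  expect_identical(r1@roc, r2@roc)
  expect_error(jackknife(toy_feature_matrix(k = 3, nPer = 1)),
               "n >= k")
})

test_that("self-consistency on separable data is perfect and shares the report schema", {
  fm <- toy_feature_matrix(k = 3, nPer = 6, sepn = 8, seed = 73)
  r <- selfConsistency(fm, kind = "svm", kernel = "linear")
  expect_equal(overallAccuracy(r), 1)
  expect_true(all(perClassTable(r)$MCC == 1))
  expect_equal(r@protocol, "self_consistency")
  j <- jackknife(fm, kind = "svm", kernel = "linear")
  expect_identical(slotNames(r), slotNames(j))
  expect_identical(names(perClassTable(r)), names(perClassTable(j)))
})

test_that("OVR ROC: perfect scores give AUC 1, chance scores give ~0.5", {
  set.seed(74)
  y <- rep(c("a", "b", "c"), each = 30)
  perfect <- sapply(c("a", "b", "c"), function(c) as.numeric(y == c))
  r <- rocOvr(y, perfect)
  expect_equal(r$auc, 1, tolerance = 1e-9)

  aucs <- sapply(1:10, function(s) {
    set.seed(s)
    sc <- matrix(rnorm(90 * 3), 90, 3, dimnames = list(NULL, c("a", "b", "c")))
    rocOvr(y, sc)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("two-class macro AUC equals the single binary AUC (cross-checked)", {
  set.seed(75)
  y <- rep(c("pos", "neg"), each = 40)
  s <- rnorm(80, mean = ifelse(y == "pos", 1, 0))
  scores <- cbind(pos = s, neg = -s)
  r <- rocOvr(y, scores)
  expect_equal(unname(r$perClassAuc["pos"]), unname(r$perClassAuc["neg"]),
               tolerance = 1e-9)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(unname(r$perClassAuc["pos"]), ref, tolerance = 1e-9)
})

test_that("macro AUC lies between the per-class extremes and flags constants", {
  set.seed(76)
  y <- rep(c("a", "b", "c"), each = 20)
  sc <- matrix(rnorm(180), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  sc[, 1] <- sc[, 1] + 2 * (y == "a")
  r <- rocOvr(y, sc)
  expect_gte(r$auc + 1e-9, min(r$perClassAuc))
  expect_lte(r$auc - 1e-9, max(r$perClassAuc))
  sc[, 2] <- 1
  expect_warning(r2 <- rocOvr(y, sc), "constant scores")
  expect_equal(unname(r2$perClassAuc["b"]), 0.5)
})

test_that("leak-free jackknife refits denoising per fold and still evaluates", {
  ps <- syntheticProteinSet(k = 2, nPerClass = 6, seed = 77)
  fm <- buildFeatureMatrix(ps, lambda = 2, xi = 1)
  spec <- WaveletSpec("db1", 1)
  r <- jackknife(fm, kind = "svm", kernel = "linear",
                 leakFree = TRUE, waveletSpec = spec)
  expect_equal(sum(confusion(r)), 12)
  expect_equal(r@protocol, "jackknife")
})
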