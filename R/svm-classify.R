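# One-vs-one multiclass SVM (binary machines via LIBSVM through e1071;
# pairing, voting and tie-breaking implemented here) plus the four
# baseline classifiers: kNN (k = 3, Euclidean), random forest (100
# trees), Gaussian naive Bayes, decision tree.

.kernel_map <- c(linear = "linear", poly3 = "polynomial",
                 rbf = "radial", sigmoid = "sigmoid")

#' Train a localization classifier
#'
#' `kind = "svm"` trains the k(k-1)/2 one-vs-one binary SVMs with the
#' requested kernel (linear, cubic polynomial, RBF or sigmoid); features
#' are used unscaled, as LIBSVM would. The baseline kinds follow their
#' stated settings: kNN with 3 Euclidean neighbors, random forest with
#' 100 trees, Gaussian naive Bayes, and a decision tree with impurity
#' defaults.
#'
#' @param fm A [FeatureMatrix] (>= 2 classes, >= 1 sample per class).
#' @param kind One of `"svm"`, `"knn"`, `"rf"`, `"nb"`, `"dt"`.
#' @param kernel SVM kernel: `"linear"` (default), `"poly3"`, `"rbf"`,
#'   `"sigmoid"`.
#' @param cost SVM cost C (default 1).
#' @param gamma Kernel coefficient for rbf/poly3/sigmoid; default 1/d.
#' @param coef0 Offset for poly3/sigmoid kernels (default 0).
#' @param k Neighbor count for kNN (default 3).
#' @param ntree Tree count for random forest (default 100).
#' @param seed Seed (needed for the random-forest baseline).
#' @return A [LocModel].
#' @export
trainClassifier <- function(fm, kind = c("svm", "knn", "rf", "nb", "dt"),
                            kernel = c("linear", "poly3", "rbf", "sigmoid"),
                            cost = 1, gamma = NULL, coef0 = 0,
                            k = 3, ntree = 100, seed = 1) {
  stopifnot(is(fm, "FeatureMatrix"))
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  X <- fm@values
  if (anyNA(X)) stop("feature matrix contains missing values")
  y <- fm@labels
  cls <- unique(y)
  if (length(cls) < 2) stop("training needs at least two classes")
  d <- ncol(X)
  if (is.null(gamma)) gamma <- 1 / d
  params <- list(cost = cost, gamma = gamma, coef0 = coef0,
                 k = k, ntree = ntree, seed = seed)
  binary <- list()
  fit <- NULL
  if (kind == "svm") {
    pairs <- utils::combn(length(cls), 2)
    binary <- lapply(seq_len(ncol(pairs)), function(p) {
      a <- cls[pairs[1, p]]; b <- cls[pairs[2, p]]
      sel <- y %in% c(a, b)
      yf <- factor(y[sel], levels = c(a, b))
      m <- e1071::svm(X[sel, , drop = FALSE], yf,
                      type = "C-classification",
                      kernel = .kernel_map[[kernel]],
                      degree = 3, cost = cost, gamma = gamma,
                      coef0 = coef0, scale = FALSE)
      list(a = a, b = b, fit = m)
    })
  } else if (kind == "knn") {
    fit <- list(X = X, y = factor(y, levels = cls))
  } else if (kind == "rf") {
    fit <- withSeed(seed, randomForest::randomForest(
      X, factor(y, levels = cls), ntree = ntree))
  } else if (kind == "nb") {
    fit <- e1071::naiveBayes(X, factor(y, levels = cls))
  } else {
    df <- data.frame(.y = factor(y, levels = cls), X, check.names = FALSE)
    fit <- rpart::rpart(.y ~ ., data = df, method = "class")
  }
  new("LocModel", kind = kind,
      kernel = if (kind == "svm") kernel else "",
      classNames = cls, binary = binary, fit = fit,
      params = params, d = as.integer(d))
}

# Signed decision value of a binary machine: positive favors class a.
.binary_decision <- function(bin, X) {
  pr <- stats::predict(bin$fit, X, decision.values = TRUE)
  dv <- as.vector(attr(pr, "decision.values"))
  nm <- colnames(attr(pr, "decision.values"))
  # LIBSVM labels the column "a/b" with positive values favoring a
  if (identical(nm, paste0(bin$b, "/", bin$a))) dv <- -dv
  dv
}

#' Predict with a LocModel
#'
#' For the one-vs-one SVM, each binary machine casts one vote; the class
#' with the most votes wins. Per-class scores are the vote counts plus a
#' bounded margin-sum term in (-0.5, 0.5) that breaks ties
#' deterministically by the aggregate signed decision value (remaining
#' exact ties fall to the lexicographically first class, with a
#' warning). Baselines return their native class scores.
#'
#' @param object A [LocModel].
#' @param newdata Numeric matrix or [FeatureMatrix] with `d` columns.
#' @param ... Unused.
#' @return List with `labels` (character) and `scores` (n x k matrix,
#'   columns named by class).
#' @export
setMethod("predict", "LocModel", function(object, newdata, ...) {
  X <- if (is(newdata, "FeatureMatrix")) newdata@values else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != object@d)
    stop("feature dimension mismatch: model expects ", object@d,
         " columns, got ", ncol(X))
  cls <- object@classNames
  k <- length(cls)
  n <- nrow(X)
  if (object@kind == "svm") {
    votes <- matrix(0, n, k, dimnames = list(NULL, cls))
    margin <- matrix(0, n, k, dimnames = list(NULL, cls))
    for (bin in object@binary) {
      dv <- .binary_decision(bin, X)
      win <- ifelse(dv > 0, bin$a, bin$b)
      for (cl in c(bin$a, bin$b))
        votes[win == cl, cl] <- votes[win == cl, cl] + 1
      margin[, bin$a] <- margin[, bin$a] + dv
      margin[, bin$b] <- margin[, bin$b] - dv
    }
    scores <- votes + 0.5 * margin / (1 + abs(margin))
    top <- apply(votes, 1, max)
    labels <- character(n)
    for (i in seq_len(n)) {
      tied <- cls[votes[i, ] == top[i]]
      if (length(tied) > 1) {
        best <- tied[margin[i, tied] == max(margin[i, tied])]
        if (length(best) > 1) {
          warning("unresolved vote/margin tie; picking ",
                  sort(best)[1])
          best <- sort(best)[1]
        }
        labels[i] <- best[1]
      } else labels[i] <- tied
    }
    return(list(labels = labels, scores = scores, votes = votes))
  }
  if (object@kind == "knn") {
    pr <- class::knn(object@fit$X, X, object@fit$y,
                     k = object@params$k, prob = TRUE)
    p <- attr(pr, "prob")
    scores <- matrix((1 - p) / max(k - 1, 1), n, k,
                     dimnames = list(NULL, cls))
    scores[cbind(seq_len(n), match(as.character(pr), cls))] <- p
    return(list(labels = as.character(pr), scores = scores))
  }
  if (object@kind == "rf") {
    scores <- stats::predict(object@fit, X, type = "prob")
    scores <- scores[, cls, drop = FALSE]
  } else if (object@kind == "nb") {
    scores <- stats::predict(object@fit, X, type = "raw")
    scores <- scores[, cls, drop = FALSE]
  } else {
    df <- as.data.frame(X, check.names = FALSE)
    scores <- stats::predict(object@fit, df, type = "prob")
    scores <- scores[, cls, drop = FALSE]
  }
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL, cls))
  labels <- cls[max.col(scores, ties.method = "first")]
  list(labels = labels, scores = scores)
})
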