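# Independent brute-force oracles, written as plain loops so they share
# no code with the package implementations.

# standardize one property column: (x - mean) / population SD
bf_standardize <- function(x) {
  mu <- sum(x) / length(x)
  sdev <- sqrt(sum((x - mu)^2) / length(x))
  (x - mu) / sdev
}

# PseAAC via direct evaluation of the defining formulas
bf_pseaac <- function(seq, lambda, omega, rawProps) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  P <- sapply(rawProps, bf_standardize)
  rownames(P) <- rownames(rawProps)
  res <- strsplit(seq, "")[[1]]
  L <- length(res)
  f <- numeric(20)
  for (u in 1:20) f[u] <- sum(res == aa[u]) / L
  theta <- function(ri, rj) {
    s <- 0
    for (p in 1:3) s <- s + (P[rj, p] - P[ri, p])^2
    s / 3
  }
  tau <- numeric(lambda)
  if (lambda > 0) for (k in 1:lambda) {
    s <- 0
    for (i in 1:(L - k)) s <- s + theta(res[i], res[i + k])
    tau[k] <- s / (L - k)
  }
  denom <- sum(f) + omega * sum(tau)
  c(f / denom, if (lambda > 0) omega * tau / denom)
}

# PsePSSM via direct loops
bf_psepssm <- function(profile, xi) {
  L <- nrow(profile)
  norm <- matrix(0, L, 20)
  for (i in 1:L) for (j in 1:20)
    norm[i, j] <- 1 / (1 + exp(-profile[i, j]))
  pbar <- numeric(20)
  for (j in 1:20) pbar[j] <- sum(norm[, j]) / L
  out <- pbar
  if (xi > 0) for (t in 1:xi) {
    th <- numeric(20)
    for (j in 1:20) {
      s <- 0
      for (i in 1:(L - t)) s <- s + (norm[i, j] - norm[i + t, j])^2
      th[j] <- s / (L - t)
    }
    out <- c(out, th)
  }
  out
}

# scalar soft / hard thresholding
bf_soft <- function(x, thr) sign(x) * max(abs(x) - thr, 0)
bf_hard <- function(x, thr) if (abs(x) > thr) x else 0

# binary-collapse metrics from raw counts
bf_metrics <- function(tp, fp, tn, fn) {
  list(sens = tp / (tp + fn), spec = tn / (tn + fp),
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

# small labeled FeatureMatrix around well-separated Gaussian blobs
toy_feature_matrix <- function(k = 3, nPer = 5, d = 6, sepn = 6,
                               seed = 99) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(c) {
    mu <- rep(0, d); mu[c] <- sepn
    matrix(rnorm(nPer * d, mean = rep(mu, each = nPer)), nPer, d)
  }))
  rownames(X) <- sprintf("s%02d", seq_len(nrow(X)))
  colnames(X) <- paste0("f", seq_len(d))
  new("FeatureMatrix", values = X,
      labels = rep(paste0("K", seq_len(k)), each = nPer),
      blocks = list(), params = list())
}

pyramid_energy <- function(p) {
  sum(p@approx^2) + sum(unlist(lapply(p@details, function(d)
    sum(d$H^2) + sum(d$V^2) + sum(d$D^2))))
}
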