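test_that("a frozen reference transform is reproduced exactly", {
  # db4, half-point symmetric extension, length-13 signal: coefficients
  # frozen from an independent reference implementation of the same
  # transform convention.
  x <- c(1.624345, -0.611756, -0.528172, -1.072969, 0.865408, -2.301539,
         1.744812, -0.761207, 0.319039, -0.249370, 1.462108, -2.060141,
         -0.322417)
  cA <- c(-0.349311751992395, -1.38482424989968, 2.18065196172878,
          -0.533689045003044, -0.614995942483806, -0.32125834121527,
          -0.278114307527034, 0.842425777043252, -0.911401232338441,
          -1.63241581727741)
  cD <- c(0.1584983950081, 0.523796338728129, 1.72930025777962,
          2.63634782627246, 0.354019858440514, 1.64613915425746,
          1.07232611716445, -1.93249844581487, -1.13452399769325,
          -0.916463119625263)
  spec <- WaveletSpec("db4", 1)
  dec <- PseLocWD:::.dwt1_multilevel(
    x, PseLocWD:::.get_filter("db4"), "symmetric", 1)
  expect_equal(dec$approx, cA, tolerance = 1e-12)
  expect_equal(dec$details[[1]], cD, tolerance = 1e-12)
})

test_that("decomposition is linear and exact on zeros; levels are bounded", {
  spec <- WaveletSpec("db4", 2)
  p <- waveletDecompose(matrix(0, 20, 24), spec)
  expect_true(all(p@approx == 0))
  expect_true(all(vapply(p@details, function(d)
    all(d$H == 0) && all(d$V == 0) && all(d$D == 0), logical(1))))
  expect_error(waveletDecompose(matrix(0, 8, 8), WaveletSpec("db8", 3)),
               "maximum admissible level")
})

test_that("Haar level-1 subbands equal the explicit 2x2 block formulas", {
  X <- outer(1:16, 1:16, function(i, j) i + 2 * j)  # ramp
  p <- waveletDecompose(X, WaveletSpec("db1", 1))
  # interior coefficients of the Haar transform: for the 2x2 block
  # (a b; c d): A=(a+b+c+d)/2, H=(a-b+c-d)/2, V=(a+b-c-d)/2, D=(a-b-c+d)/2
  for (bi in 1:8) for (bj in 1:8) {
    a <- X[2 * bi - 1, 2 * bj - 1]; b <- X[2 * bi - 1, 2 * bj]
    c2 <- X[2 * bi, 2 * bj - 1]; d <- X[2 * bi, 2 * bj]
    expect_equal(p@approx[bi, bj], (a + b + c2 + d) / 2, tolerance = 1e-12)
    expect_equal(abs(p@details[[1]]$H[bi, bj]), abs(a - b + c2 - d) / 2,
                 tolerance = 1e-12)
    expect_equal(abs(p@details[[1]]$V[bi, bj]), abs(a + b - c2 - d) / 2,
                 tolerance = 1e-12)
    expect_equal(abs(p@details[[1]]$D[bi, bj]), abs(a - b - c2 + d) / 2,
                 tolerance = 1e-12)
  }
})

test_that("perfect reconstruction holds for every family at levels 3-5 on 317x255", {
  set.seed(51)
  X <- matrix(rnorm(317 * 255), 317, 255)
  for (fam in waveletFamilies()) {
    for (J in 3:5) {
      spec <- WaveletSpec(fam, J)
      err <- max(abs(waveletReconstruct(waveletDecompose(X, spec)) - X))
      expect_lt(err, 1e-8)
    }
  }
})

test_that("Parseval holds for orthogonal families under periodic extension", {
  set.seed(52)
  X <- matrix(rnorm(64 * 96), 64, 96)
  for (fam in c("db1", "db4", "db8", "sym3", "sym7", "coif2")) {
    p <- waveletDecompose(X, WaveletSpec(fam, 2, extension = "periodic"))
    expect_lt(abs(pyramid_energy(p) - sum(X^2)) / sum(X^2), 1e-6)
  }
  expect_error(
    waveletDecompose(X, WaveletSpec("bior2.4", 1, extension = "periodic")),
    "orthogonal")
})

test_that("the universal threshold is zero on zeros, homogeneous, and recovers sigma", {
  p0 <- waveletDecompose(matrix(0, 32, 32), WaveletSpec("db4", 2))
  expect_warning(thr0 <- defaultThreshold(p0), "all zero")
  expect_equal(thr0, 0)

  set.seed(53)
  X <- matrix(rnorm(64 * 64), 64, 64)
  spec <- WaveletSpec("db8", 1)
  t1 <- defaultThreshold(waveletDecompose(X, spec))
  t3 <- defaultThreshold(waveletDecompose(3 * X, spec))
  expect_equal(t3, 3 * t1, tolerance = 1e-10)

  # MAD sigma-hat on pure unit-variance noise lands near 1
  for (s in 1:10) {
    set.seed(s)
    N <- matrix(rnorm(64 * 64), 64, 64)
    thr <- defaultThreshold(waveletDecompose(N, WaveletSpec("db8", 1)))
    sigma_hat <- thr / sqrt(2 * log(64 * 64))
    expect_gt(sigma_hat, 0.8)
    expect_lt(sigma_hat, 1.2)
  }
})

test_that("Birge-Massart thresholds equal brute-force sort-and-select", {
  set.seed(54)
  X <- matrix(rnorm(64), 8, 8)
  p <- waveletDecompose(X, WaveletSpec("db1", 2, thresholdRule = "birge-massart"))
  alpha <- 1.5
  thr <- birgeMassartThresholds(p, alpha)
  J <- 2
  M <- length(p@details[[1]]$D)
  for (t in 1:J) {
    budget <- round(M / (J + 2 - t)^alpha)
    for (dir in c("H", "V", "D")) {
      coefs <- sort(abs(as.vector(p@details[[t]][[dir]])),
                    decreasing = TRUE)
      want <- if (budget >= length(coefs)) 0 else coefs[budget + 1]
      expect_equal(unname(thr[[t]][dir]), want, tolerance = 1e-12)
    }
  }
  expect_error(birgeMassartThresholds(p, alpha = 1), "alpha")

  # coarse level: budget (M / 2^1.5 = 6) exceeds its 4 coefficients,
  # so every direction's threshold is 0 (identity at that level)
  expect_true(all(thr[[2]] == 0))

  # keep-largest semantics: the largest coefficient survives a budget of 1
  Xs <- matrix(0, 8, 8); Xs[3, 5] <- 7
  ps <- waveletDecompose(Xs, WaveletSpec("db1", 1))
  ths <- birgeMassartThresholds(ps, alpha = 3)   # budget 16/3^3 -> ~1
  out <- applyThreshold(ps, ths, mode = "hard")
  biggest <- max(abs(ps@details[[1]]$D))
  if (biggest > 0)
    expect_equal(max(abs(out@details[[1]]$D)), biggest)
})

test_that("soft and hard shrinkage match the scalar definitions", {
  expect_equal(PseLocWD:::.shrink(3, 1, "soft"), 2)
  expect_equal(PseLocWD:::.shrink(-0.5, 1, "soft"), 0)
  set.seed(55)
  X <- matrix(rnorm(32 * 32), 32, 32)
  p <- waveletDecompose(X, WaveletSpec("db4", 2))
  for (mode in c("soft", "hard")) {
    out <- applyThreshold(p, 0.7, mode = mode)
    for (t in 1:2) for (dir in c("H", "V", "D")) {
      got <- out@details[[t]][[dir]]
      ref <- p@details[[t]][[dir]]
      oracle <- if (mode == "soft") vapply(ref, bf_soft, numeric(1), thr = 0.7)
                else vapply(ref, bf_hard, numeric(1), thr = 0.7)
      expect_equal(as.vector(got), oracle, tolerance = 1e-12)
      expect_lte(sum(got^2), sum(ref^2))          # energy non-increase
      expect_true(all(abs(got) <= abs(ref) + 1e-15))
    }
    expect_identical(out@approx, p@approx)        # approximation untouched
  }
  # thr = 0 is the identity
  id <- applyThreshold(p, 0, mode = "soft")
  expect_equal(waveletReconstruct(id), X, tolerance = 1e-8)
  expect_error(applyThreshold(p, -1), "non-negative")
})

test_that("larger thresholds never increase any detail magnitude", {
  set.seed(56)
  X <- matrix(rnorm(24 * 24), 24, 24)
  p <- waveletDecompose(X, WaveletSpec("sym3", 2))
  a <- applyThreshold(p, 0.3, mode = "soft")
  b <- applyThreshold(p, 0.9, mode = "soft")
  for (t in 1:2) for (dir in c("H", "V", "D"))
    expect_true(all(abs(b@details[[t]][[dir]]) <=
                    abs(a@details[[t]][[dir]]) + 1e-15))
})

test_that("2-D denoising reduces MSE on low-rank-plus-noise fixtures", {
  spec <- WaveletSpec("db8", 4)
  wins <- 0L
  for (s in 1:10) {
    fx <- makeNoiseFixture(317, 255, rank = 3, sigma = 1, seed = s)
    dn <- denoiseMatrix(fx$noisy, spec)
    if (mean((dn - fx$clean)^2) < mean((fx$noisy - fx$clean)^2))
      wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("denoising at the operating point preserves shape and metadata", {
  fx <- makeNoiseFixture(317, 255, sigma = 0.5, seed = 7)
  out <- denoiseMatrix(fx$noisy, WaveletSpec("db8", 4))
  expect_equal(dim(out), c(317L, 255L))
  expect_true(attr(out, "thresholds") > 0)

  fm <- toy_feature_matrix()
  fmd <- denoiseMatrix(fm, WaveletSpec("db1", 1))
  expect_identical(classLabels(fmd), classLabels(fm))
  expect_identical(rownames(featureValues(fmd)), rownames(featureValues(fm)))
  expect_true(!is.null(featureParams(fmd)$thresholds))
})

test_that("1-D per-row denoising leaves constant rows alone and reduces row MSE", {
  spec <- WaveletSpec("db4", 2)
  X <- matrix(5, 3, 64)
  expect_equal(denoiseRows(X, spec), X, tolerance = 1e-8)

  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    clean <- matrix(sin(seq(0, 6 * pi, length.out = 128)), 1, 128)
    noisy <- clean + 0.4 * matrix(rnorm(128), 1, 128)
    dn <- denoiseRows(noisy, spec)
    if (mean((dn - clean)^2) < mean((noisy - clean)^2)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
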