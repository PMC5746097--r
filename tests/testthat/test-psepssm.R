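test_that("sigmoid normalization maps scores into (0,1) monotonically", {
  m <- matrix(0, 2, 20)
  expect_true(all(sigmoidNormalize(m) == 0.5))
  m <- matrix(c(-30, -3, 0, 3, 30), 5, 20)
  nm <- sigmoidNormalize(m)
  expect_true(all(nm > 0 & nm < 1))
  expect_true(all(diff(nm[, 1]) > 0))
  set.seed(31)
  f <- matrix(sample(-10:10, 60, replace = TRUE), 3, 20)
  expect_equal(sigmoidNormalize(f), 1 / (1 + exp(-f)), tolerance = 1e-15)
})

test_that("mean profile equals column means", {
  set.seed(32)
  f <- matrix(rnorm(100), 5, 20)
  nm <- sigmoidNormalize(f)
  expect_equal(unname(meanProfile(nm)), apply(nm, 2, mean),
               ignore_attr = TRUE)
  one <- sigmoidNormalize(matrix(rnorm(20), 1, 20))
  expect_equal(unname(meanProfile(one)), as.vector(one))
  const <- sigmoidNormalize(matrix(2, 7, 20))
  expect_true(all(meanProfile(const) == 1 / (1 + exp(-2))))
})

test_that("lagged correlations match brute force and detect periodicity", {
  cm <- sigmoidNormalize(matrix(1, 4, 20))
  expect_true(all(psepssmCorrelation(cm, 2) == 0))

  r1 <- rnorm(20); r2 <- rnorm(20)
  nm <- sigmoidNormalize(rbind(r1, r2, r1))
  th <- matrix(psepssmCorrelation(nm, 2), nrow = 20)
  expect_true(all(th[, 2] == 0))   # lag 2: row1 vs row3 identical
  expect_true(any(th[, 1] > 0))

  set.seed(33)
  f <- matrix(sample(-7:7, 120, replace = TRUE), 6, 20)
  expect_equal(c(meanProfile(sigmoidNormalize(f)),
                 psepssmCorrelation(sigmoidNormalize(f), 3)),
               bf_psepssm(f, 3), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PsePSSM vector obeys the 20 + 20*xi dimension law", {
  set.seed(34)
  f <- matrix(sample(-7:7, 240, replace = TRUE), 12, 20)
  expect_length(psepssmVector(f, 0), 20)
  expect_length(psepssmVector(f, 10), 220)
  expect_equal(unname(psepssmVector(f, 2)), bf_psepssm(f, 2),
               tolerance = 1e-12)
  expect_error(psepssmVector(f, 12), "xi")
  for (xi in 1:3) {
    set.seed(xi)
    g <- matrix(rnorm(200), 10, 20)
    expect_equal(unname(psepssmVector(g, xi)), bf_psepssm(g, xi),
                 tolerance = 1e-12)
  }
})

test_that("row permutation changes theta but not the mean profile", {
  set.seed(35)
  f <- matrix(sample(-7:7, 200, replace = TRUE), 10, 20)
  perm <- f[sample(10), ]
  expect_equal(meanProfile(sigmoidNormalize(f)),
               meanProfile(sigmoidNormalize(perm)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    psepssmCorrelation(sigmoidNormalize(f), 2),
    psepssmCorrelation(sigmoidNormalize(perm), 2))))
})

test_that("surrogate profiles reproduce BLOSUM62 rows and are seeded", {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  cols <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  s <- "ACDWY"
  p0 <- surrogatePssm(s, noiseSd = 0, seed = 1)
  expect_equal(unname(p0[, ]),
               unname(env$BLOSUM62[strsplit(s, "")[[1]], cols]),
               ignore_attr = TRUE)
  p1 <- surrogatePssm(s, noiseSd = 1, seed = 7)
  p2 <- surrogatePssm(s, noiseSd = 1, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p0[, ], p1[, ]))

  # noise is centered: mean deviation within 3 SE of zero
  long <- paste(rep("ACDEFGHIKL", 100), collapse = "")
  pl <- surrogatePssm(long, noiseSd = 1, seed = 3)
  base <- unname(env$BLOSUM62[strsplit(long, "")[[1]], cols])
  dev <- as.vector(pl - base)
  se <- sd(dev) / sqrt(length(dev))
  expect_lt(abs(mean(dev)), 3 * se + 1e-12)
})
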