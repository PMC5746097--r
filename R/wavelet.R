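# Multilevel separable 2-D discrete wavelet transform with soft/hard
# thresholding of the detail subbands. The default boundary policy is
# half-point symmetric extension, which keeps floor((N + flen - 1) / 2)
# coefficients per branch and reconstructs exactly for arbitrary
# (non-dyadic) sizes. A circular ("periodic") policy is available for
# orthogonal families on even lengths, where the transform is exactly
# orthonormal (Parseval holds).

#' Construct a WaveletSpec
#'
#' @param family Wavelet family (default `"db8"`, the operating point).
#' @param level Decomposition level J (default 4).
#' @param thresholdRule `"universal"` or `"birge-massart"`.
#' @param thresholdMode `"soft"` (default) or `"hard"`.
#' @param extension `"symmetric"` (default) or `"periodic"`.
#' @param alpha Birge-Massart sparsity exponent (> 1, default 1.5).
#' @return A [WaveletSpec].
#' @export
WaveletSpec <- function(family = "db8", level = 4L,
                        thresholdRule = c("universal", "birge-massart"),
                        thresholdMode = c("soft", "hard"),
                        extension = c("symmetric", "periodic"),
                        alpha = 1.5) {
  new("WaveletSpec", family = family, level = as.integer(level),
      thresholdRule = match.arg(thresholdRule),
      thresholdMode = match.arg(thresholdMode),
      extension = match.arg(extension), alpha = alpha)
}

#' Supported wavelet families
#' @return Character vector of the ten supported family names.
#' @export
waveletFamilies <- function() .wavelet_families

.get_filter <- function(family) {
  f <- .wavelet_filters[[family]]
  if (is.null(f)) stop("unsupported wavelet family: ", family)
  f
}

# Half-point symmetric extension indices for length N, pad n each side.
.sym_ext_idx <- function(N, n) {
  p <- (1 - n):(N + n)
  q <- ((p - 1) %% (2 * N)) + 1
  ifelse(q <= N, q, 2 * N + 1 - q)
}

# Analysis operators mapping a length-N signal to its coefficient
# vectors: x %*% W_lo = cA, x %*% W_hi = cD (built once per length).
.dwt_ops <- function(N, filt, extension) {
  fl <- length(filt$dec_lo)
  if (extension == "periodic") {
    if (!isTRUE(filt$orthogonal))
      stop("periodic extension is supported for orthogonal families only")
    if (N %% 2L != 0L || N < fl)
      stop("periodic extension needs an even length >= filter length (N = ",
           N, ")")
    O <- N %/% 2L
    Wlo <- matrix(0, N, O)
    Whi <- matrix(0, N, O)
    for (i in seq_len(O)) {
      pos <- ((2L * (i - 1L) + seq_len(fl) - 1L) %% N) + 1L
      Wlo[pos, i] <- Wlo[pos, i] + filt$dec_lo
      Whi[pos, i] <- Whi[pos, i] + filt$dec_hi
    }
    return(list(Wlo = Wlo, Whi = Whi, O = O, ext = seq_len(N)))
  }
  O <- (N + fl - 1L) %/% 2L
  ext <- .sym_ext_idx(N, fl - 1L)
  Ne <- length(ext)
  Wlo <- matrix(0, Ne, O)
  Whi <- matrix(0, Ne, O)
  rlo <- rev(filt$dec_lo)
  rhi <- rev(filt$dec_hi)
  for (i in seq_len(O)) {
    s <- 2L * i
    Wlo[s:(s + fl - 1L), i] <- rlo
    Whi[s:(s + fl - 1L), i] <- rhi
  }
  list(Wlo = Wlo, Whi = Whi, O = O, ext = ext)
}

# Synthesis operators: cA %*% Mlo + cD %*% Mhi reconstructs the length-N
# signal exactly.
.idwt_ops <- function(N, filt, extension) {
  fl <- length(filt$rec_lo)
  if (extension == "periodic") {
    ops <- .dwt_ops(N, filt, "periodic")
    # orthonormal circular transform: inverse = transpose
    return(list(Mlo = t(ops$Wlo), Mhi = t(ops$Whi), O = ops$O))
  }
  O <- (N + fl - 1L) %/% 2L
  # upsample -> full convolution -> trim fl-2 each side -> crop to N
  up_conv <- function(coef, f) {
    u <- numeric(2L * O)
    u[seq(1L, 2L * O, 2L)] <- coef
    y <- stats::convolve(u, rev(f), type = "open")
    y <- y[(fl - 1L):(length(y) - (fl - 2L))]
    y[seq_len(N)]
  }
  Mlo <- matrix(0, O, N)
  Mhi <- matrix(0, O, N)
  e <- numeric(O)
  for (i in seq_len(O)) {
    e[i] <- 1
    Mlo[i, ] <- up_conv(e, filt$rec_lo)
    Mhi[i, ] <- up_conv(e, filt$rec_hi)
    e[i] <- 0
  }
  list(Mlo = Mlo, Mhi = Mhi, O = O)
}

# One 2-D analysis step: returns A, H, V, D. Columns dimension (within-
# row direction) is transformed first, then rows. H carries high-pass
# along columns (horizontal variation), V high-pass along rows.
.dwt2_step <- function(X, filt, extension) {
  opc <- .dwt_ops(ncol(X), filt, extension)
  Xe <- X[, opc$ext, drop = FALSE]
  Lc <- Xe %*% opc$Wlo
  Hc <- Xe %*% opc$Whi
  opr <- .dwt_ops(nrow(X), filt, extension)
  tr <- function(M) {
    Me <- M[opr$ext, , drop = FALSE]
    list(lo = crossprod(opr$Wlo, Me), hi = crossprod(opr$Whi, Me))
  }
  l <- tr(Lc); h <- tr(Hc)
  list(A = l$lo, H = h$lo, V = l$hi, D = h$hi)
}

.idwt2_step <- function(A, H, V, D, filt, extension, shape) {
  opr <- .idwt_ops(shape[1], filt, extension)
  opc <- .idwt_ops(shape[2], filt, extension)
  Lc <- crossprod(opr$Mlo, A) + crossprod(opr$Mhi, V)   # rows inverse
  Hc <- crossprod(opr$Mlo, H) + crossprod(opr$Mhi, D)
  Lc %*% opc$Mlo + Hc %*% opc$Mhi                       # columns inverse
}

# Admissible level: decomposition may continue while the running
# approximation stays longer than filter length - 1 (the fixed point of
# the coefficient-length recursion) in both dimensions.
.max_level <- function(shape, fl, extension) {
  lens <- shape
  J <- 0L
  repeat {
    if (extension == "periodic") {
      if (any(lens %% 2L != 0L) || any(lens < fl)) break
      nxt <- lens %/% 2L
    } else {
      if (any(lens <= fl - 1L)) break
      nxt <- (lens + fl - 1L) %/% 2L
    }
    J <- J + 1L
    lens <- nxt
    if (J > 64L) break
  }
  J
}

#' Multilevel 2-D wavelet decomposition
#'
#' @param X Numeric matrix (finite entries).
#' @param spec A [WaveletSpec].
#' @return A [WaveletPyramid] with level-1 = finest detail subbands.
#' @export
waveletDecompose <- function(X, spec) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  validObject(spec)
  filt <- .get_filter(spec@family)
  fl <- length(filt$dec_lo)
  Jmax <- .max_level(dim(X), fl, spec@extension)
  if (spec@level > Jmax)
    stop("decomposition level ", spec@level, " too large for a ",
         nrow(X), " x ", ncol(X), " matrix with ", spec@family,
         " (maximum admissible level: ", Jmax, ")")
  a <- X
  details <- vector("list", spec@level)
  shapes <- matrix(0L, nrow = spec@level, ncol = 2)
  for (t in seq_len(spec@level)) {
    shapes[t, ] <- dim(a)
    st <- .dwt2_step(a, filt, spec@extension)
    details[[t]] <- list(H = st$H, V = st$V, D = st$D)
    a <- st$A
  }
  new("WaveletPyramid", approx = a, details = details,
      shapes = shapes, spec = spec)
}

#' Reconstruct a matrix from a WaveletPyramid
#'
#' Inverse of [waveletDecompose]; without thresholding the round trip is
#' exact to floating-point precision.
#'
#' @param pyramid A [WaveletPyramid].
#' @return Numeric matrix of the original shape.
#' @export
waveletReconstruct <- function(pyramid) {
  stopifnot(is(pyramid, "WaveletPyramid"))
  spec <- pyramid@spec
  filt <- .get_filter(spec@family)
  a <- pyramid@approx
  for (t in rev(seq_along(pyramid@details))) {
    d <- pyramid@details[[t]]
    a <- .idwt2_step(a, d$H, d$V, d$D, filt, spec@extension,
                     pyramid@shapes[t, ])
  }
  a
}

#' Universal ("default") denoising threshold
#'
#' thr = sigma_hat * sqrt(2 log n), with sigma_hat the median absolute
#' value of the finest diagonal subband divided by 0.6745 (the MAD
#' estimate of the noise SD) and n the total element count of the input
#' matrix. A single global threshold for all detail subbands.
#'
#' @param pyramid A [WaveletPyramid].
#' @param n Total element count of the original matrix (defaults to the
#'   shape recorded in the pyramid).
#' @return Non-negative scalar threshold.
#' @export
defaultThreshold <- function(pyramid, n = prod(pyramid@shapes[1, ])) {
  stopifnot(is(pyramid, "WaveletPyramid"))
  d1 <- pyramid@details[[1]]$D
  sigma <- stats::median(abs(d1)) / 0.6745
  if (sigma == 0) {
    warning("finest diagonal subband is all zero; threshold = 0")
    return(0)
  }
  sigma * sqrt(2 * log(n))
}

#' Birge-Massart per-level, per-direction thresholds
#'
#' For level t (1 = finest) and each direction, the retention budget is
#' round(M / (J + 2 - t)^alpha) with M the element count of a level-1
#' detail subband; the threshold is the magnitude of the (budget + 1)-th
#' largest coefficient in that subband (0 when the budget covers all
#' coefficients), so exactly the `budget` largest-magnitude coefficients
#' survive hard thresholding.
#'
#' @param pyramid A [WaveletPyramid].
#' @param alpha Sparsity exponent (> 1; default from the pyramid's spec).
#' @return List (per level) of named numeric vectors `c(H=, V=, D=)`.
#' @export
birgeMassartThresholds <- function(pyramid, alpha = pyramid@spec@alpha) {
  stopifnot(is(pyramid, "WaveletPyramid"))
  if (alpha <= 1) stop("alpha must be > 1")
  J <- length(pyramid@details)
  M <- length(pyramid@details[[1]]$D)
  lapply(seq_len(J), function(t) {
    budget <- round(M / (J + 2 - t)^alpha)
    vapply(c("H", "V", "D"), function(dir) {
      coefs <- sort(abs(as.vector(pyramid@details[[t]][[dir]])),
                    decreasing = TRUE)
      if (budget >= length(coefs)) 0
      else if (budget < 1) coefs[1]    # keep nothing: clamp at the max
      else coefs[budget + 1]
    }, numeric(1))
  })
}

.shrink <- function(x, thr, mode) {
  if (mode == "soft") sign(x) * pmax(abs(x) - thr, 0)
  else x * (abs(x) > thr)
}

#' Threshold the detail subbands of a pyramid
#'
#' Applies soft (`sign(x) * max(|x| - thr, 0)`) or hard
#' (`x * 1[|x| > thr]`) shrinkage to every detail coefficient; the
#' approximation subband is never touched.
#'
#' @param pyramid A [WaveletPyramid].
#' @param thresholds A single non-negative scalar (global), or a list as
#'   returned by [birgeMassartThresholds].
#' @param mode `"soft"` or `"hard"` (default from the pyramid's spec).
#' @return The thresholded [WaveletPyramid].
#' @export
applyThreshold <- function(pyramid, thresholds,
                           mode = pyramid@spec@thresholdMode) {
  stopifnot(is(pyramid, "WaveletPyramid"))
  mode <- match.arg(mode, c("soft", "hard"))
  J <- length(pyramid@details)
  if (!is.list(thresholds)) {
    if (length(thresholds) != 1 || thresholds < 0)
      stop("global threshold must be a single non-negative number")
    thresholds <- rep(list(c(H = thresholds, V = thresholds,
                             D = thresholds)), J)
  }
  if (length(thresholds) != J)
    stop("need one threshold set per level")
  if (any(unlist(thresholds) < 0)) stop("thresholds must be >= 0")
  for (t in seq_len(J)) {
    for (dir in c("H", "V", "D")) {
      pyramid@details[[t]][[dir]] <-
        .shrink(pyramid@details[[t]][[dir]], thresholds[[t]][[dir]], mode)
    }
  }
  pyramid
}

.denoise_core <- function(X, spec) {
  pyr <- waveletDecompose(X, spec)
  thr <- if (spec@thresholdRule == "universal") defaultThreshold(pyr)
         else birgeMassartThresholds(pyr)
  out <- waveletReconstruct(applyThreshold(pyr, thr, spec@thresholdMode))
  list(values = out, thresholds = thr)
}

#' Denoise a feature matrix as a 2-D signal
#'
#' Decompose, threshold the detail subbands per the spec's rule and
#' mode, reconstruct. The whole dataset matrix is treated as one 2-D
#' signal (the default, evaluation-faithful mode; see the vignette for
#' the train/test leakage caveat).
#'
#' @param x A [FeatureMatrix] or plain numeric matrix.
#' @param spec A [WaveletSpec] (default: db8, level 4, universal soft —
#'   the operating point).
#' @return Same type as `x`, with `attr(, "thresholds")` recording the
#'   thresholds applied (for `FeatureMatrix`, in the returned object's
#'   `params$thresholds`).
#' @export
denoiseMatrix <- function(x, spec = WaveletSpec()) {
  if (is(x, "FeatureMatrix")) {
    res <- .denoise_core(x@values, spec)
    dimnames(res$values) <- dimnames(x@values)
    x@values <- res$values
    x@params$thresholds <- res$thresholds
    return(x)
  }
  res <- .denoise_core(x, spec)
  out <- res$values
  dimnames(out) <- dimnames(x)
  attr(out, "thresholds") <- res$thresholds
  out
}

# ---- 1-D variant (per-row denoising) ----

.dwt1_multilevel <- function(x, filt, extension, J) {
  lens <- integer(J)
  details <- vector("list", J)
  a <- x
  for (t in seq_len(J)) {
    lens[t] <- length(a)
    ops <- .dwt_ops(length(a), filt, extension)
    ae <- a[ops$ext]
    details[[t]] <- as.vector(ae %*% ops$Whi)
    a <- as.vector(ae %*% ops$Wlo)
  }
  list(approx = a, details = details, lens = lens)
}

.idwt1_multilevel <- function(dec, filt, extension) {
  a <- dec$approx
  for (t in rev(seq_along(dec$details))) {
    ops <- .idwt_ops(dec$lens[t], filt, extension)
    a <- as.vector(a %*% ops$Mlo + dec$details[[t]] %*% ops$Mhi)
  }
  a
}

#' Denoise each row independently with a 1-D wavelet transform
#'
#' Same family, level, threshold rule and mode as the 2-D path, applied
#' to every row separately (the 1-D comparison arm). With the universal
#' rule, sigma is estimated per row from its finest detail coefficients
#' and n is the row length.
#'
#' @param x A [FeatureMatrix] or numeric matrix.
#' @param spec A [WaveletSpec].
#' @return Same type as `x`.
#' @export
denoiseRows <- function(x, spec = WaveletSpec()) {
  m <- if (is(x, "FeatureMatrix")) x@values else x
  filt <- .get_filter(spec@family)
  fl <- length(filt$dec_lo)
  Jmax <- .max_level(c(ncol(m), ncol(m)), fl, spec@extension)
  if (spec@level > Jmax)
    stop("decomposition level ", spec@level, " too large for rows of ",
         "length ", ncol(m), " (maximum admissible level: ", Jmax, ")")
  out <- m
  for (i in seq_len(nrow(m))) {
    dec <- .dwt1_multilevel(m[i, ], filt, spec@extension, spec@level)
    if (spec@thresholdRule == "universal") {
      sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
      thr <- if (sigma == 0) 0 else sigma * sqrt(2 * log(ncol(m)))
      dec$details <- lapply(dec$details, .shrink, thr = thr,
                            mode = spec@thresholdMode)
    } else {
      J <- spec@level
      M <- length(dec$details[[1]])
      for (t in seq_len(J)) {
        budget <- round(M / (J + 2 - t)^spec@alpha)
        coefs <- sort(abs(dec$details[[t]]), decreasing = TRUE)
        thr <- if (budget >= length(coefs)) 0
               else if (budget < 1) coefs[1]
               else coefs[budget + 1]
        dec$details[[t]] <- .shrink(dec$details[[t]], thr,
                                    spec@thresholdMode)
      }
    }
    out[i, ] <- .idwt1_multilevel(dec, filt, spec@extension)
  }
  if (is(x, "FeatureMatrix")) {
    x@values <- out
    x
  } else out
}
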