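# Pseudo-PSSM descriptor: sigmoid-normalize the L x 20 profile, take the
# 20 column means (PSSM-ACC) and append 20*xi lagged squared-difference
# correlation factors.

#' Sigmoid-normalize a PSSM
#'
#' Elementwise 1 / (1 + exp(-x)) applied to the raw log-odds scores,
#' mapping every entry into (0, 1).
#'
#' @param profile L x 20 numeric matrix of raw PSSM scores.
#' @return Matrix of the same shape with entries in (0, 1).
#' @export
sigmoidNormalize <- function(profile) {
  stopifnot(is.matrix(profile), ncol(profile) == 20)
  out <- 1 / (1 + exp(-profile))
  dimnames(out) <- dimnames(profile)
  out
}

#' Mean profile (PSSM-ACC)
#'
#' @param norm Sigmoid-normalized PSSM.
#' @return The 20 column means.
#' @export
meanProfile <- function(norm) {
  stopifnot(is.matrix(norm), ncol(norm) == 20, nrow(norm) >= 1)
  colMeans(norm)
}

#' Lagged PsePSSM correlation factors
#'
#' For tier t = 1..xi and column j:
#' theta_j^t = mean over i of (norm\[i, j\] - norm\[i + t, j\])^2,
#' concatenated tier-major (all 20 columns of tier 1, then tier 2, ...).
#'
#' @param norm Sigmoid-normalized PSSM (L rows).
#' @param xi Number of tiers, 1 <= xi < L.
#' @return Numeric vector of length 20 * xi.
#' @export
psepssmCorrelation <- function(norm, xi) {
  L <- nrow(norm)
  if (xi < 1 || xi >= L)
    stop("xi must satisfy 1 <= xi < L (L = ", L, ")")
  unlist(lapply(seq_len(xi), function(t) {
    d <- norm[seq_len(L - t), , drop = FALSE] -
         norm[t + seq_len(L - t), , drop = FALSE]
    colMeans(d^2)
  }), use.names = FALSE)
}

#' Pseudo-PSSM feature vector
#'
#' Concatenation of the 20 column means of the sigmoid-normalized PSSM
#' and the 20*xi lagged correlation factors: 20 + 20*xi values. xi = 0
#' yields the plain PSSM-ACC vector.
#'
#' @param profile L x 20 raw PSSM matrix.
#' @param xi Tier count (default 10, the operating point).
#' @return Named numeric vector of length 20 + 20*xi.
#' @export
psepssmVector <- function(profile, xi = 10) {
  L <- nrow(profile)
  if (xi < 0 || xi >= L)
    stop("xi must satisfy 0 <= xi < L (L = ", L, ")")
  norm <- sigmoidNormalize(profile)
  v <- meanProfile(norm)
  nm <- paste0("mean.", .pssm_columns)
  if (xi > 0) {
    v <- c(v, psepssmCorrelation(norm, xi))
    nm <- c(nm, paste0("theta", rep(seq_len(xi), each = 20), ".",
                       rep(.pssm_columns, xi)))
  }
  stats::setNames(unname(v), nm)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Surrogate PSSM profile
#'
#' Stands in for a database-search profile when none is available:
#' row i is the BLOSUM62 substitution-score row of residue i (in
#' PSI-BLAST column order) plus independent Gaussian noise, rounded to
#' integers. Deterministic given `seed`. Synthetic profiles only; real
#' profiles are read with [readPssm].
#'
#' @param seq Sanitized residue string.
#' @param noiseSd Gaussian noise standard deviation (default 1).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return L x 20 integer-valued matrix, PSI-BLAST column order.
#' @export
surrogatePssm <- function(seq, noiseSd = 1, seed = NULL) {
  res <- strsplit(seq, "")[[1]]
  if (!all(res %in% .aa_alphabet))
    stop("sequence must be sanitized to the 20-letter alphabet")
  b <- .blosum62()
  base <- b[res, .pssm_columns, drop = FALSE]
  gen <- function() {
    if (noiseSd > 0)
      base <- base + matrix(stats::rnorm(length(base), sd = noiseSd),
                            nrow = nrow(base))
    round(base)
  }
  out <- if (is.null(seed)) gen() else withSeed(seed, gen())
  rownames(out) <- NULL
  colnames(out) <- .pssm_columns
  attr(out, "residues") <- res
  out
}

#' Attach surrogate profiles to every record of a ProteinSet
#'
#' @param ps A [ProteinSet].
#' @param noiseSd Noise SD passed to [surrogatePssm].
#' @param seed Integer seed for the whole set (one RNG stream).
#' @return The `ProteinSet` with `profiles` filled.
#' @export
attachSurrogateProfiles <- function(ps, noiseSd = 1, seed = 1) {
  stopifnot(is(ps, "ProteinSet"))
  seqs <- as.character(ps@sequences)
  prof <- withSeed(seed, lapply(seqs, surrogatePssm,
                                noiseSd = noiseSd, seed = NULL))
  names(prof) <- names(ps@sequences)
  ps@profiles <- prof
  validObject(ps)
  ps
}

# Run code under a temporary RNG state; restores the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
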