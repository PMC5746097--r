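# Seeded synthetic datasets: multi-class sequence sets with
# class-conditional residue-composition biases plus surrogate profiles,
# and low-rank-plus-noise matrix fixtures for the denoising tests.

#' Generate a labeled synthetic ProteinSet
#'
#' One shared base residue distribution is drawn from a symmetric
#' Dirichlet; each class then tilts it, upweighting a class-specific
#' residue triplet by the factor 1 + `separation` (triplets are disjoint
#' across classes for k <= 6). Class signal therefore enters through
#' composition and, via the residue-indexed surrogate profiles, through
#' the PsePSSM block as well. Sequences are i.i.d. draws of
#' uniform-random length within `lengthRange`. `separation = 0` leaves
#' every class sampling the same base distribution (chance-level data).
#'
#' @param k Number of classes (default 4).
#' @param nPerClass Sequences per class (default 30).
#' @param lengthRange Integer range of sequence lengths (default 50-150;
#'   minimum must be >= 50 so lambda = 15 and xi = 10 are admissible
#'   with margin).
#' @param separation Dirichlet concentration added on each class triplet
#'   (default 10, strongly separated classes).
#' @param profileNoiseSd Surrogate-profile noise SD (default 1).
#' @param seed Integer seed (required; the generator is deterministic).
#' @return A [ProteinSet] with labels `C1..Ck` and attached profiles.
#' @export
syntheticProteinSet <- function(k = 4, nPerClass = 30,
                                lengthRange = c(50, 150),
                                separation = 10, profileNoiseSd = 1,
                                seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (lengthRange[1] > lengthRange[2])
    stop("impossible length range: min > max")
  if (lengthRange[1] < 50)
    stop("minimum length must be >= 50")
  withSeed(seed, {
    cls <- paste0("C", seq_len(k))
    # disjoint residue triplets per class (cycled when k > 6)
    triplets <- lapply(seq_len(k), function(c)
      ((3 * (c - 1) + 0:2) %% 20) + 1)
    g <- stats::rgamma(20, shape = 2)
    base <- g / sum(g)
    seqs <- character(0)
    labs <- character(0)
    for (c in seq_len(k)) {
      w <- rep(1, 20)
      w[triplets[[c]]] <- 1 + separation
      p <- base * w / sum(base * w)
      for (r in seq_len(nPerClass)) {
        L <- sample(lengthRange[1]:lengthRange[2], 1)
        seqs <- c(seqs, paste(sample(.aa_alphabet, L, replace = TRUE,
                                     prob = p), collapse = ""))
        labs <- c(labs, cls[c])
      }
    }
    names(seqs) <- sprintf("seq_%04d", seq_along(seqs))
    ps <- ProteinSet(seqs, labels = labs, classNames = cls)
    prof <- lapply(as.character(ps@sequences), surrogatePssm,
                   noiseSd = profileNoiseSd, seed = NULL)
    names(prof) <- names(ps@sequences)
    ps@profiles <- prof
    validObject(ps)
    ps
  })
}

#' Low-rank clean matrix plus Gaussian noise fixture
#'
#' `clean` is a sum of `rank` outer products of smooth (sinusoidal)
#' vectors; `noisy = clean + sigma * N(0, 1)` elementwise. The default
#' shape matches the dataset-level feature-matrix geometry (317 x 255).
#'
#' @param rows,cols Matrix shape (defaults 317, 255).
#' @param rank Rank of the clean matrix (<= min(rows, cols), default 3).
#' @param sigma Noise SD (default 1).
#' @param seed Integer seed.
#' @return List with matrices `clean` and `noisy`.
#' @export
makeNoiseFixture <- function(rows = 317, cols = 255, rank = 3,
                             sigma = 1, seed = 1) {
  if (rank > min(rows, cols)) stop("rank must be <= min(rows, cols)")
  withSeed(seed, {
    clean <- matrix(0, rows, cols)
    for (r in seq_len(rank)) {
      u <- sin(seq(0, r * pi, length.out = rows)) + 0.3 * r
      v <- cos(seq(0, (rank - r + 1) * pi, length.out = cols))
      clean <- clean + u %o% v
    }
    noisy <- clean + sigma * matrix(stats::rnorm(rows * cols), rows, cols)
    list(clean = clean, noisy = noisy)
  })
}
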