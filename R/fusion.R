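# Fuse the PseAAC and PsePSSM blocks into the dataset-level n x d matrix,
# d = (20 + lambda) + (20 + 20 * xi).

#' Build the fused feature matrix for a labeled ProteinSet
#'
#' Each row is the concatenation of the protein's PseAAC vector
#' (20 + lambda) and its PsePSSM vector (20 + 20*xi); at the operating
#' point lambda = 15, xi = 10 this is 35 + 220 = 255 columns.
#'
#' @param ps A [ProteinSet] with labels for every record.
#' @param lambda PseAAC tier count (default 15).
#' @param omega PseAAC weight factor (default 0.05).
#' @param xi PsePSSM tier count (default 10).
#' @param profileSource `"attached"` uses the profiles stored in `ps`
#'   (all must be present); `"surrogate"` generates BLOSUM62-based
#'   surrogate profiles on the fly.
#' @param noiseSd Surrogate profile noise SD.
#' @param seed Seed for surrogate profile generation.
#' @param props Standardized property table for PseAAC.
#' @return A [FeatureMatrix].
#' @export
buildFeatureMatrix <- function(ps, lambda = 15, omega = 0.05, xi = 10,
                               profileSource = c("attached", "surrogate"),
                               noiseSd = 1, seed = 1,
                               props = standardizeProperties(aaPropertyTable())) {
  stopifnot(is(ps, "ProteinSet"))
  profileSource <- match.arg(profileSource)
  ids <- names(ps@sequences)
  lab <- ps@labels
  if (anyNA(lab))
    stop("every record needs a class label; missing for: ",
         paste(ids[is.na(lab)], collapse = ", "))
  seqs <- as.character(ps@sequences)
  L <- nchar(seqs)
  short <- ids[L <= max(lambda, xi)]
  if (length(short))
    stop("sequences too short for lambda = ", lambda, ", xi = ", xi,
         " (need L > max(lambda, xi)): ", paste(short, collapse = ", "))
  if (profileSource == "attached") {
    miss <- setdiff(ids, names(ps@profiles))
    if (length(miss))
      stop("profiles missing for: ", paste(miss, collapse = ", "))
    prof <- ps@profiles[ids]
  } else {
    prof <- withSeed(seed, lapply(seqs, surrogatePssm,
                                  noiseSd = noiseSd, seed = NULL))
    names(prof) <- ids
  }
  d1 <- 20L + as.integer(lambda)
  d2 <- 20L + 20L * as.integer(xi)
  v <- matrix(NA_real_, nrow = length(ids), ncol = d1 + d2,
              dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    v[i, ] <- c(pseaacVector(seqs[i], lambda, omega, props),
                psepssmVector(prof[[i]], xi))
  }
  colnames(v) <- c(paste0("pseaac.", seq_len(d1)),
                   paste0("psepssm.", seq_len(d2)))
  new("FeatureMatrix", values = v, labels = lab,
      blocks = list(pseaac = seq_len(d1), psepssm = d1 + seq_len(d2)),
      params = list(lambda = lambda, omega = omega, xi = xi))
}
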