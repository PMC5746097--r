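# Chou's pseudo-amino-acid composition: 20 residue frequencies plus
# lambda sequence-order correlation factors built from hydrophobicity,
# hydrophilicity and side-chain mass.

#' Amino-acid property table
#'
#' Returns the bundled hydrophobicity (H1), hydrophilicity (H2) and
#' side-chain mass (M) values for the 20 amino acids — the canonical
#' table used by the PseAAC web server. A user table with the same
#' columns may be supplied instead.
#'
#' @param path Optional path to a TSV with columns `aa H1 H2 M`
#'   (defaults to the bundled fixture).
#' @return Data frame with rownames = amino acids and columns H1, H2, M.
#' @export
aaPropertyTable <- function(path = system.file("extdata",
                                               "aa_properties.tsv",
                                               package = "PseLocWD")) {
  tab <- utils::read.delim(path, colClasses = c("character", rep("numeric", 3)))
  if (!all(c("aa", "H1", "H2", "M") %in% names(tab)))
    stop("property table needs columns aa, H1, H2, M")
  if (!setequal(tab$aa, .aa_alphabet))
    stop("property table must cover exactly the 20 standard amino acids")
  rownames(tab) <- tab$aa
  tab[.aa_alphabet, c("H1", "H2", "M")]
}

#' Standardize a property table
#'
#' Each property column is transformed to zero mean and unit standard
#' deviation over the 20 amino acids (population SD, Chou's convention).
#' Idempotent.
#'
#' @param raw Data frame from [aaPropertyTable] (or already standardized).
#' @return Standardized data frame, same shape.
#' @export
standardizeProperties <- function(raw) {
  out <- raw
  for (j in seq_along(out)) {
    x <- out[[j]]
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))
    if (sdev == 0)
      stop("cannot standardize a constant property column: ",
           names(out)[j])
    out[[j]] <- (x - mu) / sdev
  }
  out
}

.props_matrix <- function(props) {
  m <- as.matrix(props)
  if (is.null(rownames(m)) || !all(.aa_alphabet %in% rownames(m)))
    stop("standardized property table must be indexed by amino acid")
  m[.aa_alphabet, , drop = FALSE]
}

#' Pairwise residue correlation function
#'
#' Theta(Ri, Rj) = mean over the three standardized properties of the
#' squared property difference (Chou's type-1 form).
#'
#' @param ri,rj Single amino-acid letters.
#' @param props Standardized property table ([standardizeProperties]).
#' @return Non-negative scalar.
#' @export
correlationTheta <- function(ri, rj, props) {
  m <- .props_matrix(props)
  if (!ri %in% rownames(m) || !rj %in% rownames(m))
    stop("unknown residue: ", ri, " / ", rj)
  mean((m[rj, ] - m[ri, ])^2)
}

#' k-tier sequence correlation factors
#'
#' tau_k = mean over i of Theta(R_i, R_{i+k}) for k = 1..lambda.
#'
#' @param seq Sanitized residue string.
#' @param lambda Number of tiers, 0 <= lambda < nchar(seq).
#' @param props Standardized property table.
#' @return Numeric vector of length `lambda` (empty when lambda = 0).
#' @export
tauFactors <- function(seq, lambda, props) {
  L <- nchar(seq)
  if (lambda < 0 || lambda >= L)
    stop("lambda must satisfy 0 <= lambda < L (L = ", L,
         ", so max lambda = ", L - 1L, ")")
  if (lambda == 0) return(numeric(0))
  m <- .props_matrix(props)
  pr <- m[strsplit(seq, "")[[1]], , drop = FALSE]
  vapply(seq_len(lambda), function(k) {
    d <- pr[seq_len(L - k), , drop = FALSE] -
         pr[k + seq_len(L - k), , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
}

#' Pseudo-amino-acid composition vector
#'
#' The (20 + lambda)-component descriptor: the first 20 components are
#' the weighted amino-acid frequencies, the remaining lambda components
#' the weighted sequence-order correlation factors; all share the
#' denominator sum(f) + omega * sum(tau), so the vector sums to one.
#'
#' @param seq Sanitized residue string.
#' @param lambda Tier count (default 15, the operating point).
#' @param omega Weight factor (> 0, default 0.05).
#' @param props Standardized property table; defaults to the bundled one.
#' @return Named numeric vector of length 20 + lambda.
#' @export
pseaacVector <- function(seq, lambda = 15, omega = 0.05,
                         props = standardizeProperties(aaPropertyTable())) {
  if (!nzchar(seq)) stop("empty sequence")
  if (omega <= 0) stop("omega must be > 0")
  L <- nchar(seq)
  res <- strsplit(seq, "")[[1]]
  if (!all(res %in% .aa_alphabet))
    stop("sequence must be sanitized to the 20-letter alphabet")
  f <- as.numeric(table(factor(res, levels = .aa_alphabet))) / L
  tau <- tauFactors(seq, lambda, props)
  denom <- sum(f) + omega * sum(tau)
  p <- c(f, omega * tau) / denom
  names(p) <- c(.aa_alphabet,
                if (lambda > 0) paste0("tau", seq_len(lambda)))
  p
}

#' Maximum admissible lambda for a sequence length
#'
#' @param L Sequence length.
#' @return L - 1 (tiers must be shorter than the sequence).
#' @export
maxLambda <- function(L) as.integer(L - 1L)
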