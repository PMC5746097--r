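#' @import methods
NULL

# 20-letter alphabet (alphabetical) and the PSI-BLAST PSSM column order
.aa_alphabet <- c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y")
.pssm_columns <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

.wavelet_families <- c("db1","db4","db8","sym3","sym7",
                       "coif2","coif4","bior1.1","bior2.4","bior3.3")

#' ProteinSet: labeled protein sequences with optional PSSM profiles
#'
#' Container for a set of protein sequences (as an
#' [Biostrings::AAStringSet]) together with optional class labels and
#' optional per-sequence L x 20 PSSM score matrices (PSI-BLAST column
#' order A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @slot sequences An `AAStringSet`; names are the sequence identifiers.
#' @slot labels Character vector parallel to `sequences` (`NA` allowed).
#' @slot classNames Ordered character vector of distinct class names.
#' @slot profiles Named list of L x 20 numeric matrices, names matching
#'   sequence identifiers; may be empty.
#'
#' @exportClass ProteinSet
setClass("ProteinSet",
  representation(
    sequences = "AAStringSet",
    labels = "character",
    classNames = "character",
    profiles = "list"
  )
)

setValidity("ProteinSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (n > 0 && (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))))
    msg <- c(msg, "sequence identifiers must be unique non-empty strings")
  if (length(object@labels) != n)
    msg <- c(msg, "labels must be parallel to sequences")
  bad <- setdiff(unique(object@labels[!is.na(object@labels)]),
                 object@classNames)
  if (length(bad))
    msg <- c(msg, paste0("labels not in classNames: ",
                         paste(bad, collapse = ", ")))
  seqs <- as.character(object@sequences)
  ok <- vapply(seqs, function(s)
    nchar(s) >= 1L &&
      all(strsplit(s, "")[[1]] %in% .aa_alphabet), logical(1))
  if (n > 0 && !all(ok))
    msg <- c(msg, paste0("sequences outside the 20-letter alphabet: ",
                         paste(ids[!ok], collapse = ", ")))
  if (length(object@profiles)) {
    pid <- names(object@profiles)
    if (is.null(pid) || !all(pid %in% ids))
      msg <- c(msg, "profile names must match sequence identifiers")
    for (id in pid) {
      p <- object@profiles[[id]]
      if (!is.matrix(p) || ncol(p) != 20L)
        msg <- c(msg, paste0("profile ", id, " must be an L x 20 matrix"))
      else if (nrow(p) != nchar(seqs[match(id, ids)]))
        msg <- c(msg, paste0("profile ", id, " has ", nrow(p),
                             " rows but the sequence has length ",
                             nchar(seqs[match(id, ids)])))
    }
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: fused per-protein descriptor matrix
#'
#' An n x d numeric matrix whose rows are proteins and whose columns are
#' the fused PseAAC block (20+lambda columns) followed by the PsePSSM
#' block (20+20*xi columns). Row identifiers, class labels, the column
#' block spans and the extraction parameters are carried along.
#'
#' @slot values Numeric n x d matrix, rownames = protein identifiers.
#' @slot labels Character vector of class names, one per row.
#' @slot blocks Named list of integer column index vectors
#'   (`pseaac`, `psepssm`).
#' @slot params Named list with `lambda`, `omega`, `xi`.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    labels = "character",
    blocks = "list",
    params = "list"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "values must be finite with no missing entries")
  if (length(object@labels) != nrow(v))
    msg <- c(msg, "one label per row required")
  if (anyNA(object@labels) || any(!nzchar(object@labels)))
    msg <- c(msg, "every row must carry a class label")
  if (is.null(rownames(v)) && nrow(v) > 0)
    msg <- c(msg, "rownames (protein identifiers) required")
  if (length(object@blocks)) {
    span <- as.integer(sort(unlist(object@blocks, use.names = FALSE)))
    if (!identical(span, seq_len(ncol(v))))
      msg <- c(msg, "column blocks must partition the columns")
  }
  if (length(msg)) msg else TRUE
})

#' WaveletSpec: wavelet denoising configuration
#'
#' @slot family Wavelet family, one of db1, db4, db8, sym3, sym7, coif2,
#'   coif4, bior1.1, bior2.4, bior3.3.
#' @slot level Decomposition level J (>= 1).
#' @slot thresholdRule `"universal"` (single global threshold, the
#'   MAD-based sigma-hat * sqrt(2 log n) rule) or `"birge-massart"`
#'   (per-level, per-direction keep-largest budgets).
#' @slot thresholdMode `"soft"` or `"hard"`.
#' @slot extension Boundary policy: `"symmetric"` (half-point, default)
#'   or `"periodic"` (circular; orthogonal families, even lengths).
#' @slot alpha Birge-Massart sparsity exponent (> 1).
#'
#' @exportClass WaveletSpec
setClass("WaveletSpec",
  representation(
    family = "character",
    level = "integer",
    thresholdRule = "character",
    thresholdMode = "character",
    extension = "character",
    alpha = "numeric"
  )
)

setValidity("WaveletSpec", function(object) {
  msg <- character()
  if (!object@family %in% .wavelet_families)
    msg <- c(msg, paste0("unsupported wavelet family '", object@family,
                         "'; supported: ",
                         paste(.wavelet_families, collapse = ", ")))
  if (object@level < 1L) msg <- c(msg, "level must be >= 1")
  if (!object@thresholdRule %in% c("universal", "birge-massart"))
    msg <- c(msg, "thresholdRule must be 'universal' or 'birge-massart'")
  if (!object@thresholdMode %in% c("soft", "hard"))
    msg <- c(msg, "thresholdMode must be 'soft' or 'hard'")
  if (!object@extension %in% c("symmetric", "periodic"))
    msg <- c(msg, "extension must be 'symmetric' or 'periodic'")
  if (object@alpha <= 1) msg <- c(msg, "alpha must be > 1")
  if (length(msg)) msg else TRUE
})

#' WaveletPyramid: multilevel 2-D wavelet coefficients
#'
#' Approximation subband plus per-level horizontal/vertical/diagonal
#' detail subbands, with the bookkeeping needed for exact reconstruction.
#' Level 1 is the finest scale.
#'
#' @slot approx Approximation subband at the coarsest level.
#' @slot details List (level 1..J) of lists with matrices `H`, `V`, `D`.
#' @slot shapes Integer matrix of the input shape entering each level.
#' @slot spec The [WaveletSpec] used for decomposition.
#'
#' @exportClass WaveletPyramid
setClass("WaveletPyramid",
  representation(
    approx = "matrix",
    details = "list",
    shapes = "matrix",
    spec = "WaveletSpec"
  )
)

#' LocModel: trained multiclass localization classifier
#'
#' For `kind = "svm"` this holds the k(k-1)/2 one-vs-one binary LIBSVM
#' machines; for the baseline kinds it holds the native fitted object.
#'
#' @slot kind One of svm, knn, rf, nb, dt.
#' @slot kernel SVM kernel (linear, poly3, rbf, sigmoid); "" otherwise.
#' @slot classNames Class names in training order.
#' @slot binary List of one-vs-one binary classifiers (svm only).
#' @slot fit Native fitted object (baselines) or training data (knn).
#' @slot params Hyperparameters used.
#' @slot d Feature dimension the model was trained on.
#'
#' @exportClass LocModel
setClass("LocModel",
  representation(
    kind = "character",
    kernel = "character",
    classNames = "character",
    binary = "list",
    fit = "ANY",
    params = "list",
    d = "integer"
  )
)

setValidity("LocModel", function(object) {
  msg <- character()
  k <- length(object@classNames)
  if (k < 2) msg <- c(msg, "at least two classes required")
  if (object@kind == "svm" &&
      length(object@binary) != k * (k - 1) / 2)
    msg <- c(msg, "one-vs-one svm must hold k(k-1)/2 binary classifiers")
  if (length(msg)) msg else TRUE
})

#' EvalReport: evaluation results for a localization model
#'
#' @slot confusion k x k integer matrix, rows = true class.
#' @slot perClass Data frame with per-class Sens, Spec, MCC.
#' @slot oa Overall accuracy (fraction, trace/n).
#' @slot mccMacro Macro-averaged per-class MCC.
#' @slot roc Data frame `fpr`, `tpr`: OVR macro-averaged ROC curve.
#' @slot perClassAuc Named per-class OVR AUCs.
#' @slot auc Trapezoidal area under the macro-averaged ROC curve.
#' @slot protocol `"jackknife"` or `"self_consistency"`.
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    confusion = "matrix",
    perClass = "data.frame",
    oa = "numeric",
    mccMacro = "numeric",
    roc = "data.frame",
    perClassAuc = "numeric",
    auc = "numeric",
    protocol = "character"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (any(object@confusion < 0)) msg <- c(msg, "negative confusion counts")
  if (object@oa < 0 || object@oa > 1) msg <- c(msg, "OA outside [0, 1]")
  if (length(object@auc) && !is.na(object@auc) &&
      (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "AUC outside [0, 1]")
  if (!object@protocol %in% c("jackknife", "self_consistency"))
    msg <- c(msg, "unknown protocol")
  if (length(msg)) msg else TRUE
})
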