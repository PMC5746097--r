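#' @rdname ProteinSet
#' @param object,x An object.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ProteinSet
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname ProteinSet
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname ProteinSet
#' @param value Replacement value.
#' @export
setGeneric("profiles<-", function(x, value) standardGeneric("profiles<-"))

#' @rdname FeatureMatrix
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' @rdname FeatureMatrix
#' @export
setGeneric("featureParams", function(x) standardGeneric("featureParams"))

#' @rdname EvalReport
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname EvalReport
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname EvalReport
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname EvalReport
#' @export
setGeneric("rocCurve", function(x) standardGeneric("rocCurve"))

#' @rdname LocModel
#' @export
setGeneric("nBinaryClassifiers",
           function(x) standardGeneric("nBinaryClassifiers"))

# ---- accessors ----

#' @rdname ProteinSet
#' @export
setMethod("classLabels", "ProteinSet", function(x) x@labels)

#' @rdname ProteinSet
#' @export
setMethod("classNames", "ProteinSet", function(x) x@classNames)

#' @rdname ProteinSet
#' @export
setMethod("profiles", "ProteinSet", function(x) x@profiles)

#' @rdname ProteinSet
#' @export
setReplaceMethod("profiles", "ProteinSet", function(x, value) {
  x@profiles <- value
  validObject(x)
  x
})

#' @rdname ProteinSet
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @rdname ProteinSet
#' @export
setMethod("names", "ProteinSet", function(x) names(x@sequences))

#' Extract sequences from a ProteinSet
#'
#' @param x A `ProteinSet`.
#' @return The underlying `AAStringSet`.
#' @export
sequencesOf <- function(x) {
  stopifnot(is(x, "ProteinSet"))
  x@sequences
}

#' @rdname FeatureMatrix
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix
#' @export
setMethod("featureBlocks", "FeatureMatrix", function(x) x@blocks)

#' @rdname FeatureMatrix
#' @export
setMethod("featureParams", "FeatureMatrix", function(x) x@params)

#' @rdname FeatureMatrix
#' @export
setMethod("classLabels", "FeatureMatrix", function(x) x@labels)

#' @rdname FeatureMatrix
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' @rdname EvalReport
#' @export
setMethod("confusion", "EvalReport", function(x) x@confusion)

#' @rdname EvalReport
#' @export
setMethod("overallAccuracy", "EvalReport", function(x) x@oa)

#' @rdname EvalReport
#' @export
setMethod("aucValue", "EvalReport", function(x) x@auc)

#' @rdname EvalReport
#' @export
setMethod("rocCurve", "EvalReport", function(x) x@roc)

#' Per-class metric table of an EvalReport
#'
#' @param x An `EvalReport`.
#' @return Data frame with one row per class: Sens, Spec, MCC.
#' @export
perClassTable <- function(x) {
  stopifnot(is(x, "EvalReport"))
  x@perClass
}

#' @rdname LocModel
#' @export
setMethod("nBinaryClassifiers", "LocModel", function(x) length(x@binary))

#' @rdname LocModel
#' @export
setMethod("classNames", "LocModel", function(x) x@classNames)

# ---- show methods ----

setMethod("show", "ProteinSet", function(object) {
  n <- length(object@sequences)
  cat("ProteinSet with", n, "sequences\n")
  if (n) {
    L <- Biostrings::width(object@sequences)
    cat("  lengths:", min(L), "-", max(L), "\n")
  }
  if (length(object@classNames)) {
    tab <- table(factor(object@labels, levels = object@classNames))
    cat("  classes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  profiles attached:", length(object@profiles), "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  d <- dim(object@values)
  p <- object@params
  cat("FeatureMatrix:", d[1], "proteins x", d[2], "features\n")
  cat("  blocks:",
      paste(names(object@blocks),
            vapply(object@blocks, length, integer(1)),
            sep = "=", collapse = ", "), "\n")
  if (length(p))
    cat("  params: lambda=", p$lambda, " omega=", p$omega,
        " xi=", p$xi, "\n", sep = "")
})

setMethod("show", "WaveletSpec", function(object) {
  cat("WaveletSpec:", object@family, "level", object@level,
      "|", object@thresholdRule, object@thresholdMode,
      "| extension", object@extension, "\n")
})

setMethod("show", "WaveletPyramid", function(object) {
  cat("WaveletPyramid:", length(object@details), "levels,",
      object@spec@family, "\n")
  cat("  approx:", paste(dim(object@approx), collapse = " x "), "\n")
})

setMethod("show", "LocModel", function(object) {
  cat("LocModel:", object@kind)
  if (object@kind == "svm")
    cat(" (", object@kernel, " kernel, ", length(object@binary),
        " one-vs-one binary classifiers)", sep = "")
  cat("\n  classes:", paste(object@classNames, collapse = ", "), "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport [", object@protocol, "]\n", sep = "")
  tab <- object@perClass
  tab$Sens <- sprintf("%.4f", tab$Sens)
  tab$Spec <- sprintf("%.4f", tab$Spec)
  tab$MCC <- sprintf("%.4f", tab$MCC)
  print(tab, row.names = FALSE)
  cat(sprintf("OA = %.4f (%.2f%%)   macro-MCC = %.4f", object@oa,
              100 * object@oa, object@mccMacro))
  if (length(object@auc) && !is.na(object@auc))
    cat(sprintf("   AUC = %.4f", object@auc))
  cat("\n")
})
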