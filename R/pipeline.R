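# End-to-end runs (extract -> denoise -> classify -> evaluate) and
# single-axis parameter sweeps, with JSON run manifests.

#' Run the full localization pipeline
#'
#' Builds the fused feature matrix, denoises it (2-D by default, 1-D per
#' row, or not at all), evaluates with the requested protocol, and
#' optionally writes feature tables, report JSON/TSV, ROC points and a
#' run manifest to `outDir`.
#'
#' @param ps A labeled [ProteinSet].
#' @param lambda,omega,xi Feature-extraction parameters (defaults 15,
#'   0.05, 10 — the operating point).
#' @param waveletSpec A [WaveletSpec] (default db8, level 4, universal
#'   soft threshold).
#' @param denoise `"2d"` (default), `"1d"`, or `"none"`.
#' @param classifier,kernel,cost Classifier settings (default linear
#'   one-vs-one SVM, C = 1).
#' @param protocol `"jackknife"` (default) or `"self_consistency"`.
#' @param leakFree Refit denoising inside each jackknife fold instead of
#'   denoising the full matrix once (default FALSE, the faithful mode).
#' @param profileSource `"attached"` or `"surrogate"` (see
#'   [buildFeatureMatrix]).
#' @param seed Seed for surrogate profiles / stochastic classifiers.
#' @param outDir Optional output directory for artifacts.
#' @return List: `report` ([EvalReport]), `features`, `denoised`
#'   ([FeatureMatrix]), `manifest` (named list echoing every parameter
#'   and the thresholds applied).
#' @export
runPipeline <- function(ps, lambda = 15, omega = 0.05, xi = 10,
                        waveletSpec = WaveletSpec(),
                        denoise = c("2d", "1d", "none"),
                        classifier = "svm", kernel = "linear", cost = 1,
                        protocol = c("jackknife", "self_consistency"),
                        leakFree = FALSE,
                        profileSource = c("attached", "surrogate"),
                        seed = 1, outDir = NULL) {
  denoise <- match.arg(denoise)
  protocol <- match.arg(protocol)
  profileSource <- match.arg(profileSource)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  fm <- stage("extract",
              buildFeatureMatrix(ps, lambda, omega, xi,
                                 profileSource = profileSource,
                                 seed = seed))
  dn <- fm
  if (denoise == "2d" && !(protocol == "jackknife" && leakFree))
    dn <- stage("denoise", denoiseMatrix(fm, waveletSpec))
  else if (denoise == "1d")
    dn <- stage("denoise", denoiseRows(fm, waveletSpec))
  report <- stage("evaluate", {
    if (protocol == "jackknife")
      jackknife(dn, kind = classifier, kernel = kernel, cost = cost,
                seed = seed,
                leakFree = (denoise == "2d" && leakFree),
                waveletSpec = if (denoise == "2d" && leakFree)
                  waveletSpec else NULL)
    else
      selfConsistency(dn, kind = classifier, kernel = kernel,
                      cost = cost, seed = seed)
  })
  manifest <- list(
    n = nrow(fm@values), d = ncol(fm@values),
    lambda = lambda, omega = omega, xi = xi,
    wavelet = waveletSpec@family, level = waveletSpec@level,
    thresholdRule = waveletSpec@thresholdRule,
    thresholdMode = waveletSpec@thresholdMode,
    extension = waveletSpec@extension,
    denoise = denoise, leakFree = leakFree,
    thresholds = dn@params$thresholds,
    classifier = classifier, kernel = kernel, cost = cost,
    protocol = protocol, profileSource = profileSource, seed = seed,
    oa = report@oa, mccMacro = report@mccMacro, auc = report@auc)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureTable(fm, file.path(outDir, "features.tsv"))
    writeFeatureTable(dn, file.path(outDir, "features_denoised.tsv"))
    writeReport(report, file.path(outDir, "report"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, features = fm, denoised = dn, manifest = manifest)
}

#' Write an EvalReport as JSON and TSV
#'
#' The TSV mirrors the per-class table layout (one row per class with
#' Sens/Spec/MCC, an OA footer); ROC points go to a separate TSV.
#'
#' @param report An [EvalReport].
#' @param stem Output path stem; writes `<stem>.json`, `<stem>.tsv`,
#'   `<stem>_roc.tsv`.
#' @export
writeReport <- function(report, stem) {
  stopifnot(is(report, "EvalReport"))
  out <- list(protocol = report@protocol,
              confusion = unclass(report@confusion),
              perClass = report@perClass,
              oa = report@oa, mccMacro = report@mccMacro,
              perClassAuc = as.list(report@perClassAuc),
              auc = report@auc)
  jsonlite::write_json(out, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tab <- report@perClass
  utils::write.table(tab, paste0(stem, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat(sprintf("OA\t%.6f\nmacroMCC\t%.6f\nAUC\t%.6f\n",
              report@oa, report@mccMacro, report@auc),
      file = paste0(stem, ".tsv"), append = TRUE)
  utils::write.table(report@roc, paste0(stem, "_roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' Sweep one pipeline parameter
#'
#' Runs the pipeline once per value of a single axis (lambda, xi,
#' wavelet family, decomposition level, SVM kernel, or classifier kind),
#' holding everything else at the supplied defaults, and collects one
#' row per grid point with the feature dimension, per-class
#' sensitivities and OA. Grid points that violate sequence-length bounds
#' are marked skipped rather than aborting the sweep.
#'
#' @param ps A labeled [ProteinSet].
#' @param param One of `"lambda"`, `"xi"`, `"wavelet"`, `"level"`,
#'   `"kernel"`, `"classifier"`.
#' @param values Vector of grid values.
#' @param ... Remaining arguments passed to [runPipeline].
#' @return Data frame, one row per grid point.
#' @export
sweepParameter <- function(ps, param = c("lambda", "xi", "wavelet",
                                         "level", "kernel", "classifier"),
                           values, ...) {
  param <- match.arg(param)
  base <- list(...)
  rows <- lapply(values, function(v) {
    args <- c(list(ps = ps), base)
    if (param == "lambda") args$lambda <- v
    else if (param == "xi") args$xi <- v
    else if (param == "kernel") args$kernel <- v
    else if (param == "classifier") args$classifier <- v
    else {
      spec <- if (!is.null(base$waveletSpec)) base$waveletSpec
              else WaveletSpec()
      if (param == "wavelet") spec@family <- as.character(v)
      else spec@level <- as.integer(v)
      validObject(spec)
      args$waveletSpec <- spec
    }
    res <- tryCatch(do.call(runPipeline, args), error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(param = param, value = as.character(v),
                        d = NA_integer_, oa = NA_real_,
                        status = paste("skipped:",
                                       conditionMessage(res)),
                        stringsAsFactors = FALSE))
    sens <- res$report@perClass$Sens
    names(sens) <- paste0("Sens.", res$report@perClass$class)
    cbind(data.frame(param = param, value = as.character(v),
                     d = res$manifest$d, oa = res$report@oa,
                     status = "ok", stringsAsFactors = FALSE),
          as.data.frame(as.list(sens)))
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(cols, names(r))) r[[m]] <- NA_real_
    r[cols]
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
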