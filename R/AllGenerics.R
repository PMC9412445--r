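#' Frame timestamps of a session
#'
#' @param x a \linkS4class{BandPowerSession}.
#' @return Numeric vector of frame right-edge timestamps in seconds.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Frame labels of a session
#'
#' @param x a \linkS4class{BandPowerSession}.
#' @return Character vector of per-frame attention labels
#'   (\code{"internal"}, \code{"external"} or \code{"none"}).
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))

#' Feature matrix of a session
#'
#' Flattens the electrode-by-band frames into the classifier's input
#' layout: one row per frame, 20 columns in electrode-major order
#' (\code{\link{featureNames}}).
#'
#' @param x a \linkS4class{BandPowerSession}.
#' @return Numeric matrix, frames x 20, with feature names as column names
#'   and frame timestamps as row names.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "BandPowerSession",
          function(x) SummarizedExperiment::colData(x)$timestamp_s)

#' @rdname frameLabels
#' @export
setMethod("frameLabels", "BandPowerSession",
          function(x) SummarizedExperiment::colData(x)$label)

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "BandPowerSession", function(x) {
  m <- t(SummarizedExperiment::assay(x, "logpower"))
  rownames(m) <- format(frameTimes(x), trim = TRUE)
  m
})

setMethod("show", "BandPowerSession", function(object) {
  n <- ncol(object)
  dur <- if (n) max(frameTimes(object)) else 0
  lab <- table(factor(frameLabels(object),
                      levels = c(attentionLevels(), "none")))
  cat(sprintf("BandPowerSession: %d frames (%.1f s at %d Hz)\n",
              n, dur, FRAME_RATE_HZ))
  cat(sprintf("  labels: external %d, internal %d, none %d\n",
              lab[["external"]], lab[["internal"]], lab[["none"]]))
  cat(sprintf("  features: %d (%s ...)\n", nrow(object),
              paste(head(rownames(object), 3), collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "AttentionLda", function(object) {
  cat(sprintf("AttentionLda: %d features, priors ext %.3f / int %.3f\n",
              length(object@featureOrder),
              object@priors[["external"]], object@priors[["internal"]]))
  top <- order(abs(object@weights), decreasing = TRUE)[1:min(3, length(object@weights))]
  cat("  largest |weights|:",
      paste(sprintf("%s (%.3g)", object@featureOrder[top],
                    object@weights[top]), collapse = ", "), "\n")
  if (length(object@dropped))
    cat("  dropped zero-variance features:",
        paste(object@dropped, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: %d-fold %s CV on %d vectors\n",
              length(object@foldAccuracy), object@scheme, object@n))
  cat(sprintf("  mean accuracy %.4f (folds: %s)\n", object@meanAccuracy,
              paste(sprintf("%.3f", object@foldAccuracy), collapse = " ")))
  invisible(NULL)
})

#' Per-fold accuracies of a calibration result
#' @param x a \linkS4class{CalibrationResult}.
#' @return Numeric vector of per-fold accuracies.
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))

#' @rdname foldAccuracies
#' @export
setMethod("foldAccuracies", "CalibrationResult", function(x) x@foldAccuracy)

#' Mean cross-validated accuracy
#' @param x a \linkS4class{CalibrationResult}.
#' @return Scalar mean accuracy in [0, 1].
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname meanAccuracy
#' @export
setMethod("meanAccuracy", "CalibrationResult", function(x) x@meanAccuracy)

#' Model coefficients of a trained discriminant
#' @param object an \linkS4class{AttentionLda}.
#' @param ... unused.
#' @return Named list with \code{weights}, \code{bias}, \code{means},
#'   \code{covariance}, \code{priors}, \code{featureOrder}.
#' @export
setMethod("coef", "AttentionLda", function(object, ...) {
  list(weights = setNames(object@weights, object@featureOrder),
       bias = object@bias, means = object@means,
       covariance = object@covariance, priors = object@priors,
       featureOrder = object@featureOrder)
})
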