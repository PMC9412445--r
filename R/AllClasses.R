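#' BandPowerSession: a labeled 10 Hz band-power stream
#'
#' An S4 container for one recording session of band-power frames, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"logpower"}
#' holds log10 band power with the 20 electrode-by-band features as rows
#' (electrode-major order, see \code{\link{featureNames}}) and one column
#' per 100 ms frame. \code{colData} carries \code{timestamp_s} (the frame's
#' right edge, seconds from session start; each frame summarises the
#' half-open window [t - 1 s, t)) and \code{label} (\code{"internal"},
#' \code{"external"} or \code{"none"}). \code{metadata} carries the session
#' plan, generator/extraction parameters, seed and format version.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{synthesizeBandPower}}, \code{\link{computeBandPowers}},
#'   \code{\link{frameTimes}}, \code{\link{frameLabels}},
#'   \code{\link{featureMatrix}}
#' @export
setClass("BandPowerSession", contains = "SummarizedExperiment")

setValidity("BandPowerSession", function(object) {
  msg <- character()
  if (!"logpower" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'logpower' is required")
  if (nrow(object) != 20L ||
      !identical(rownames(object), featureNames()))
    msg <- c(msg, "rows must be the 20 canonical features in electrode-major order")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("timestamp_s", "label") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'timestamp_s' and 'label'")
  } else {
    if (ncol(object) > 1 && is.unsorted(cd$timestamp_s, strictly = TRUE))
      msg <- c(msg, "'timestamp_s' must be strictly increasing")
    if (!all(cd$label %in% c(attentionLevels(), "none")))
      msg <- c(msg, "labels must be 'internal', 'external' or 'none'")
  }
  if (length(msg)) msg else TRUE
})

# internal constructor shared by the generator, the extractor and the reader
newBandPowerSession <- function(logpower, timestamps, labels,
                                meta = list()) {
  stopifnot(is.matrix(logpower), nrow(logpower) == 20L)
  rownames(logpower) <- featureNames()
  el <- rep(museElectrodes(), each = 5L)
  bd <- rep(bandDefinitions()$band, times = 4L)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logpower = logpower),
    rowData = S4Vectors::DataFrame(electrode = el, band = bd,
                                   row.names = featureNames()),
    colData = S4Vectors::DataFrame(timestamp_s = as.numeric(timestamps),
                                   label = as.character(labels))
  )
  obj <- methods::new("BandPowerSession", se)
  S4Vectors::metadata(obj) <- meta
  obj
}

#' AttentionLda: a trained two-class linear discriminant
#'
#' Gaussian classes with a shared pooled within-class covariance and
#' empirical class priors yield an affine decision function
#' \eqn{s(x) = w'x + b} with \eqn{w = \Sigma^{-1}(\mu_{int} - \mu_{ext})}
#' and \eqn{b} placing the boundary at the prior-adjusted midpoint. A frame
#' is called \emph{internal} iff \eqn{s(x) > 0}; the tie \eqn{s(x) = 0}
#' goes to \emph{external}, matching the pipeline's bias toward not pausing.
#'
#' @slot weights numeric feature weight vector.
#' @slot bias numeric scalar intercept.
#' @slot means 2 x d matrix of class means (rows \code{external},
#'   \code{internal}).
#' @slot covariance d x d pooled within-class covariance.
#' @slot priors named numeric(2) class priors, summing to 1.
#' @slot featureOrder character vector naming the features the model expects,
#'   in order.
#' @slot dropped character vector of zero-variance features removed before
#'   training (their weight is 0 by construction).
#' @seealso \code{\link{trainAttentionLda}}, \code{\link{crossValidate}}
#' @export
setClass("AttentionLda",
  representation(weights = "numeric", bias = "numeric", means = "matrix",
                 covariance = "matrix", priors = "numeric",
                 featureOrder = "character", dropped = "character"))

setValidity("AttentionLda", function(object) {
  msg <- character()
  d <- length(object@featureOrder)
  if (length(object@weights) != d)
    msg <- c(msg, "weights length must match featureOrder")
  if (length(object@bias) != 1L) msg <- c(msg, "bias must be a scalar")
  if (!identical(dim(object@means), c(2L, d)))
    msg <- c(msg, "means must be 2 x d")
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1")
  if (!identical(names(object@priors), attentionLevels()))
    msg <- c(msg, "priors must be named external, internal (in that order)")
  if (length(msg)) msg else TRUE
})

#' CalibrationResult: k-fold cross-validated calibration accuracy
#'
#' @slot foldAccuracy numeric per-fold accuracies, in [0, 1].
#' @slot meanAccuracy arithmetic mean of the fold accuracies.
#' @slot scheme \code{"shuffled"} or \code{"contiguous"} fold assignment.
#' @slot n number of feature vectors.
#' @slot classBalance named numeric(2), class proportions.
#' @slot seed seed used for shuffling.
#' @seealso \code{\link{crossValidate}}
#' @export
setClass("CalibrationResult",
  representation(foldAccuracy = "numeric", meanAccuracy = "numeric",
                 scheme = "character", n = "integer",
                 classBalance = "numeric", seed = "integer"))

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (any(object@foldAccuracy < 0 | object@foldAccuracy > 1))
    msg <- c(msg, "fold accuracies must lie in [0, 1]")
  if (abs(object@meanAccuracy - mean(object@foldAccuracy)) > 1e-12)
    msg <- c(msg, "meanAccuracy must equal the mean of foldAccuracy")
  if (length(msg)) msg else TRUE
})
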