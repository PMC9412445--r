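#' Muse electrode montage
#'
#' The four electrode names of the Muse headband, in the fixed order used
#' throughout the package (feature vectors are electrode-major in this
#' order).
#'
#' @return Character vector \code{c("TP9", "AF7", "AF8", "TP10")}.
#' @export
#' @examples
#' museElectrodes()
museElectrodes <- function() c("TP9", "AF7", "AF8", "TP10")

#' Canonical EEG band definitions
#'
#' The five frequency bands streamed by Mind-Monitor-style band-power
#' sources: delta (1--4 Hz), theta (4--8 Hz), alpha (7.5--13 Hz), beta
#' (13--30 Hz), gamma (30--44 Hz). Band edges are closed on both sides;
#' note that the printed theta and alpha ranges overlap between 7.5 and
#' 8 Hz, and adjacent ranges share their common edge. Spectral bins falling
#' in an overlap contribute to both bands.
#'
#' @return A data.frame with columns \code{band}, \code{low}, \code{high}
#'   (Hz), one row per band in the fixed order delta, theta, alpha, beta,
#'   gamma.
#' @export
#' @examples
#' bandDefinitions()
bandDefinitions <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 7.5, 13, 30),
    high = c(4, 8, 13, 30, 44),
    stringsAsFactors = FALSE
  )
}

#' Feature names in canonical order
#'
#' Electrode-major flattening of the 4 x 5 electrode-by-band grid:
#' \code{tp9_delta}, \code{tp9_theta}, ..., \code{tp10_gamma}. Element
#' (e, b) of the grid (0-based) lands at flat index \code{5 * e + b + 1}.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' featureNames()[1:6]
featureNames <- function() {
  el <- tolower(museElectrodes())
  bd <- bandDefinitions()$band
  as.vector(t(outer(el, bd, paste, sep = "_")))
}

# Attention state levels, in the fixed factor order used everywhere.
# "external" first so that tie-breaks toward external are the first level.
attentionLevels <- function() c("external", "internal")

# Frame cadence of the band-power stream (frames per second).
FRAME_RATE_HZ <- 10
# Width of each frame's analysis window in seconds.
FRAME_WINDOW_S <- 1
# Linear-power floor applied before taking log10.
POWER_FLOOR <- 1e-12
# Session file format version tag.
SESSION_FORMAT_VERSION <- "1"
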