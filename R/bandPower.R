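#' Feature-extraction configuration
#'
#' The extractor mirrors the consumer-headband convention: an FFT on a
#' 256-sample Hamming window, sliding at 10 Hz, i.e. one band-power frame
#' every 100 ms summarising the previous second. At 256 Hz the nominal
#' step of 25.6 samples is not an integer; frames are therefore scheduled
#' on the exact 100 ms time grid and each takes the most recent 256
#' samples, so realized steps alternate between 25 and 26 samples while
#' consecutive windows still overlap by 90\%.
#'
#' @param windowLength analysis window in samples (default 256).
#' @param frameRate frames per second (default 10).
#' @param padStart if TRUE (default), frames in the first second use a
#'   zero-padded left edge, so a T-second recording yields exactly
#'   \code{10 * T} frames (e.g. 4000 from a 400 s calibration session).
#'   If FALSE, frames are emitted only once a full window is available.
#' @param powerFloor linear-power floor applied before log10
#'   (default 1e-12), so all-zero windows stay finite.
#' @return A validated list of class \code{"FeatureConfig"}.
#' @export
featureConfig <- function(windowLength = 256L, frameRate = 10,
                          padStart = TRUE, powerFloor = POWER_FLOOR) {
  stopIfNot(windowLength >= 2 && windowLength == round(windowLength),
            "'windowLength' must be an integer >= 2")
  stopIfNot(frameRate > 0, "'frameRate' must be > 0")
  structure(list(windowLength = as.integer(windowLength),
                 frameRate = frameRate, padStart = isTRUE(padStart),
                 powerFloor = powerFloor),
            class = "FeatureConfig")
}

# Symmetric Hamming taper: 0.54 - 0.46 cos(2 pi k / (n - 1)).
hammingTaper <- function(n) as.numeric(signal::hamming(n))

#' Extract band powers from raw EEG
#'
#' For every 100 ms frame, each channel's most recent \code{windowLength}
#' samples are Hamming-tapered, Fourier transformed, and converted to a
#' one-sided periodogram normalized by the taper's power
#' (\code{sum(w^2)}), so that the total periodogram sum estimates the
#' signal variance. Band power is the sum of periodogram bins whose center
#' frequency f satisfies \code{low <= f <= high} (closed on both edges;
#' bins in the printed theta/alpha overlap count toward both bands), then
#' log10-transformed with a floor.
#'
#' @param raw a \linkS4class{RawEeg}.
#' @param cfg a \code{\link{featureConfig}}.
#' @param bands band definitions (default \code{\link{bandDefinitions}}).
#' @return A \linkS4class{BandPowerSession}; labels are \code{"none"}
#'   until \code{\link{labelFrames}} is applied.
#' @export
#' @examples
#' raw <- synthesizeRaw(makeSessionPlan(1, 3, 3, seed = 1))
#' sess <- computeBandPowers(raw)
#' ncol(sess)   # 60 frames from 6 s
computeBandPowers <- function(raw, cfg = featureConfig(),
                              bands = bandDefinitions()) {
  stopIfNot(methods::is(raw, "RawEeg"), "'raw' must be a RawEeg")
  stopIfNot(inherits(cfg, "FeatureConfig"),
            "'cfg' must come from featureConfig()")
  x <- raw@signal
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x))[1L]
    stop(sprintf("non-finite sample at index %d (channel %s)",
                 (bad - 1L) %% nrow(x) + 1L,
                 colnames(x)[(bad - 1L) %/% nrow(x) + 1L]), call. = FALSE)
  }
  fs <- raw@samplingRate
  nw <- cfg$windowLength
  nTot <- nrow(x)
  nFrames <- floor(nTot / fs * cfg$frameRate)
  ends <- floor(seq_len(nFrames) * fs / cfg$frameRate)
  if (!cfg$padStart) ends <- ends[ends >= nw]
  if (length(ends) == 0L) {
    warning("signal shorter than one analysis window: empty stream")
    return(newBandPowerSession(
      matrix(numeric(0), nrow = 20, ncol = 0), numeric(0), character(0),
      list(plan = raw@plan, seed = raw@seed, source = "extracted",
           version = SESSION_FORMAT_VERSION)))
  }
  w <- hammingTaper(nw)
  norm <- sum(w^2)
  f <- (seq_len(nw) - 1L) * fs / nw
  half <- f <= fs / 2
  sideFactor <- ifelse(f == 0 | f == fs / 2, 1, 2)
  binSets <- lapply(seq_len(nrow(bands)), function(b)
    which(half & f >= bands$low[b] & f <= bands$high[b]))

  # one big windowed matrix: nw x (frames * channels), FFT'd column-wise
  win <- matrix(0, nrow = nw, ncol = length(ends) * 4L)
  for (e in 1:4) {
    for (k in seq_along(ends)) {
      i1 <- ends[k] - nw + 1L
      seg <- x[max(i1, 1L):ends[k], e]
      col <- (e - 1L) * length(ends) + k
      win[(nw - length(seg) + 1L):nw, col] <- seg
    }
  }
  P <- abs(stats::mvfft(win * w))^2 / (nw * norm)
  logp <- matrix(NA_real_, nrow = 20, ncol = length(ends))
  for (e in 1:4) {
    cols <- (e - 1L) * length(ends) + seq_along(ends)
    for (b in 1:5) {
      bp <- colSums(P[binSets[[b]], cols, drop = FALSE] *
                      sideFactor[binSets[[b]]])
      logp[(e - 1L) * 5L + b, ] <- log10(pmax(bp, cfg$powerFloor))
    }
  }
  meta <- list(plan = raw@plan, seed = raw@seed, source = "extracted",
               featureConfig = unclass(cfg),
               version = SESSION_FORMAT_VERSION)
  meta$config_hash <- configHash(meta[c("featureConfig", "seed", "source")])
  newBandPowerSession(logp, ends / fs, rep("none", length(ends)), meta)
}

#' Attach ground-truth labels to a session's frames
#'
#' Each frame's label is the attention state covering the majority of its
#' 1 s analysis window (clipped to the plan's extent); exact ties go to
#' external. Frames whose window lies entirely outside the labeled phases
#' are dropped, with the dropped count reported as a message and recorded
#' in the session metadata.
#'
#' @param session a \linkS4class{BandPowerSession}.
#' @param plan a session plan from \code{\link{makeSessionPlan}}.
#' @return The relabeled (possibly shortened) session.
#' @export
labelFrames <- function(session, plan) {
  lab <- labelForWindow(frameTimes(session), plan)
  drop <- lab == "none"
  if (any(drop))
    message(sprintf("dropped %d frame(s) outside labeled phases", sum(drop)))
  out <- session[, !drop]
  SummarizedExperiment::colData(out)$label <- lab[!drop]
  meta <- S4Vectors::metadata(out)
  meta$plan <- plan
  meta$droppedUnlabeled <- sum(drop)
  S4Vectors::metadata(out) <- meta
  out
}
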