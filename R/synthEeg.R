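#' RawEeg: a multichannel time-domain EEG segment
#'
#' @slot signal numeric matrix, samples x 4 channels, column names TP9,
#'   AF7, AF8, TP10; units are arbitrary amplitude (the band-power scale
#'   downstream is log10 of summed periodogram power).
#' @slot samplingRate sampling rate in Hz.
#' @slot plan the session plan the segment was generated from (may have
#'   zero rows for unlabeled data).
#' @slot seed integer seed used for generation (NA for external data).
#' @seealso \code{\link{synthesizeRaw}}, \code{\link{computeBandPowers}}
#' @export
setClass("RawEeg",
  representation(signal = "matrix", samplingRate = "numeric",
                 plan = "data.frame", seed = "integer"))

setValidity("RawEeg", function(object) {
  msg <- character()
  if (ncol(object@signal) != 4L ||
      !identical(colnames(object@signal), museElectrodes()))
    msg <- c(msg, "signal must have 4 columns named TP9, AF7, AF8, TP10")
  if (object@samplingRate <= 2 * max(bandDefinitions()$high))
    msg <- c(msg, sprintf(
      "sampling rate must exceed twice the top band edge (%g Hz)",
      2 * max(bandDefinitions()$high)))
  if (length(msg)) msg else TRUE
})

setMethod("show", "RawEeg", function(object) {
  cat(sprintf("RawEeg: %d samples x 4 channels at %g Hz (%.1f s)\n",
              nrow(object@signal), object@samplingRate,
              nrow(object@signal) / object@samplingRate))
  invisible(NULL)
})

#' Parameters of the synthetic EEG generator
#'
#' The generator's native scale is log10 band power ("absolute" band values
#' as streamed by Mind-Monitor-style sources are treated as log-scale;
#' their true units are not documented, so this convention is an explicit
#' package choice). Each electrode x band cell has a baseline log-power;
#' internally directed attention adds \code{internalShift}, by default an
#' alpha-band increase largest at the right temporoparietal electrode TP10,
#' reflecting the right-parietal alpha increase associated with internal
#' focus. Frame-to-frame variability is i.i.d. Gaussian on the log scale.
#'
#' @param baseline 4 x 5 matrix (electrodes x bands) of baseline log10
#'   power, or a length-5 per-band vector recycled across electrodes.
#'   Default: delta 1.3, theta 1.0, alpha 0.9, beta 0.7, gamma 0.4 --
#'   the usual monotone 1/f-like decline of EEG band power.
#' @param internalShift 4 x 5 matrix of additive log-power offsets applied
#'   on internal frames, or a length-4 per-electrode vector applied to the
#'   alpha band only. Default alpha shifts: TP9 0.30, AF7 0.10, AF8 0.10,
#'   TP10 0.60 -- a right-lateralized temporoparietal alpha increase whose
#'   Mahalanobis separation at the default noise SD
#'   (|shift|/noiseSd = 1.96) puts the Bayes accuracy of the downstream
#'   discriminant near 84\%, the calibration level typical of this kind
#'   of person-dependent consumer-EEG setup. Use 0 for a null (no-effect)
#'   generator.
#' @param noiseSd standard deviation of the per-frame log-power noise
#'   (default 0.35).
#' @param samplingRate raw-signal sampling rate in Hz (default 256); must
#'   exceed twice the top band edge.
#' @param crossfadeS raw-signal cross-fade at phase boundaries in seconds
#'   (default 0.05).
#' @return A list of validated generator parameters, class
#'   \code{"GeneratorParams"}.
#' @export
#' @examples
#' generatorParams()                      # study-like defaults
#' generatorParams(internalShift = 0)     # null model
generatorParams <- function(baseline = c(1.3, 1.0, 0.9, 0.7, 0.4),
                            internalShift = c(0.30, 0.10, 0.10, 0.60),
                            noiseSd = 0.35,
                            samplingRate = 256,
                            crossfadeS = 0.05) {
  if (!is.matrix(baseline)) {
    stopIfNot(length(baseline) %in% c(1L, 5L),
              "'baseline' must be a 4x5 matrix or a per-band vector")
    baseline <- matrix(rep(baseline, length.out = 5), nrow = 4, ncol = 5,
                       byrow = TRUE)
  }
  stopIfNot(all(dim(baseline) == c(4, 5)), "'baseline' must be 4 x 5")
  if (!is.matrix(internalShift)) {
    stopIfNot(length(internalShift) %in% c(1L, 4L),
              "'internalShift' must be a 4x5 matrix, a per-electrode alpha vector, or a scalar")
    sh <- matrix(0, 4, 5)
    sh[, 3] <- rep(internalShift, length.out = 4)  # alpha column
    internalShift <- sh
  }
  stopIfNot(all(dim(internalShift) == c(4, 5)),
            "'internalShift' must be 4 x 5")
  stopIfNot(is.numeric(noiseSd) && length(noiseSd) == 1 && noiseSd >= 0,
            "'noiseSd' must be >= 0")
  stopIfNot(samplingRate > 2 * max(bandDefinitions()$high),
            "sampling rate must exceed twice the top band edge")
  dimnames(baseline) <- dimnames(internalShift) <-
    list(museElectrodes(), bandDefinitions()$band)
  structure(list(baseline = baseline, internalShift = internalShift,
                 noiseSd = noiseSd, samplingRate = samplingRate,
                 crossfadeS = crossfadeS),
            class = "GeneratorParams")
}

# flatten an electrodes x bands matrix into canonical electrode-major order
flattenGrid <- function(m) as.vector(t(m))

#' Generate a labeled band-power session directly at the frame level
#'
#' Draws one 4 x 5 log-power frame per 100 ms: each electrode x band cell
#' is Gaussian with mean = baseline (+ internal shift on internal frames)
#' and SD \code{noiseSd}. Frame labels follow the majority-coverage rule:
#' a frame at time t summarises [t - 1 s, t) and takes the state covering
#' most of that window, ties going to external.
#'
#' @param plan a session plan from \code{\link{makeSessionPlan}}.
#' @param params generator parameters from \code{\link{generatorParams}}.
#' @param seed integer seed; defaults to the plan's seed. The actual RNG
#'   stream is the named child stream \code{"bandpower"} of this seed.
#' @return A \linkS4class{BandPowerSession} with
#'   \code{floor(duration x 10)} frames.
#' @export
#' @examples
#' sess <- synthesizeBandPower(makeSessionPlan(4, 50, 50, seed = 1))
#' ncol(sess)   # 4000 frames from 400 s
synthesizeBandPower <- function(plan, params = generatorParams(),
                                seed = attr(plan, "seed")) {
  stopIfNot(inherits(params, "GeneratorParams"),
            "'params' must come from generatorParams()")
  total <- planDuration(plan)
  n <- floor(total * FRAME_RATE_HZ)
  t <- seq_len(n) / FRAME_RATE_HZ
  labels <- labelForWindow(t, plan)
  base <- flattenGrid(params$baseline)
  shift <- flattenGrid(params$internalShift)
  mu <- matrix(base, nrow = 20, ncol = n)
  mu[, labels == "internal"] <- base + shift
  noise <- withSeed(childSeed(seed, "bandpower"),
                    matrix(rnorm(20L * n, sd = params$noiseSd), nrow = 20))
  meta <- list(plan = plan, params = unclass(params),
               seed = as.integer(seed), source = "synthetic-bandpower",
               version = SESSION_FORMAT_VERSION)
  meta$config_hash <- configHash(meta[c("params", "seed", "source")])
  newBandPowerSession(mu + noise, t, labels, meta)
}

#' Generate a labeled raw EEG segment
#'
#' Synthesizes each channel as a sum over the five bands of band-limited
#' Gaussian noise whose variance equals the target linear band power
#' (10^baseline, plus the internal shift during internal phases). Band
#' limiting is done by FFT-domain masking (spectrum zeroed outside the
#' band) per contiguous phase segment; segments are joined with short
#' equal-power cosine cross-fades to avoid boundary discontinuities.
#'
#' The scaling is chosen so that the band-power extractor
#' (\code{\link{computeBandPowers}}, windowed-periodogram band sums)
#' recovers the target log powers on average, up to the spectral overlap
#' of adjacent bands.
#'
#' @inheritParams synthesizeBandPower
#' @return A \linkS4class{RawEeg} with
#'   \code{floor(duration x samplingRate)} samples per channel.
#' @export
#' @examples
#' raw <- synthesizeRaw(makeSessionPlan(1, 5, 5, seed = 7))
#' dim(raw@signal)   # 2560 x 4
synthesizeRaw <- function(plan, params = generatorParams(),
                          seed = attr(plan, "seed")) {
  stopIfNot(inherits(params, "GeneratorParams"),
            "'params' must come from generatorParams()")
  fs <- params$samplingRate
  bands <- bandDefinitions()
  nTot <- floor(planDuration(plan) * fs)
  fade <- max(2L, round(params$crossfadeS * fs))
  segStart <- floor(plan$start_s * fs) + 1L
  segEnd <- c(floor(plan$end_s * fs)[-nrow(plan)], nTot)

  sig <- withSeed(childSeed(seed, "raw"), {
    out <- matrix(0, nrow = nTot, ncol = 4)
    for (e in 1:4) {
      segs <- vector("list", nrow(plan))
      for (i in seq_len(nrow(plan))) {
        len <- segEnd[i] - segStart[i] + 1L
        pad <- if (i < nrow(plan)) fade else 0L
        x <- numeric(len + pad)
        internal <- plan$state[i] == "internal"
        for (b in seq_len(nrow(bands))) {
          p <- 10^(params$baseline[e, b] +
                     if (internal) params$internalShift[e, b] else 0)
          x <- x + bandLimitedNoise(len + pad, fs, bands$low[b],
                                    bands$high[b], p)
        }
        segs[[i]] <- x
      }
      ch <- numeric(nTot)
      for (i in seq_len(nrow(plan))) {
        idx <- segStart[i]:segEnd[i]
        ch[idx] <- segs[[i]][seq_along(idx)]
        if (i < nrow(plan)) {
          # equal-power cross-fade over the first `fade` samples of the
          # next segment, blending in this segment's padded tail
          j <- segEnd[i] + seq_len(min(fade, nTot - segEnd[i]))
          th <- (seq_along(j) - 0.5) / fade * (pi / 2)
          tailPrev <- segs[[i]][length(segs[[i]]) - fade + seq_along(j)]
          ch[j] <- cos(th) * tailPrev + sin(th) * segs[[i + 1L]][seq_along(j)]
        }
      }
      out[, e] <- ch
    }
    out
  })
  colnames(sig) <- museElectrodes()
  methods::new("RawEeg", signal = sig, samplingRate = fs, plan = plan,
               seed = as.integer(seed))
}

# Gaussian noise of length n, band-limited to [low, high] Hz by FFT
# masking, scaled to variance `power`. Bins whose (aliased) frequency lies
# in the closed band are kept.
bandLimitedNoise <- function(n, fs, low, high, power) {
  z <- rnorm(n)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  mask <- f >= low & f <= high
  x <- Re(fft(fft(z) * mask, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x * sqrt(power) / s
}

#' Stream corruption parameters
#'
#' Consumer-headband streams arrive with imperfections: Bluetooth delay
#' and timestamp jitter, and a small fraction of missing samples. Defaults
#' sit mid-range of the imperfections reported for the Muse headband:
#' 0.01--0.05\% missing samples, 5 ms jitter, 20--40 ms delay.
#'
#' @param missingRate fraction of samples/frames dropped independently,
#'   in [0, 1] (default 3e-4).
#' @param jitterSd SD of Gaussian timestamp jitter in seconds
#'   (default 0.005).
#' @param blockDelay constant stream delay in seconds (default 0.03).
#' @return A validated list of class \code{"CorruptionParams"}.
#' @export
corruptionParams <- function(missingRate = 3e-4, jitterSd = 0.005,
                             blockDelay = 0.03) {
  stopIfNot(is.numeric(missingRate) && missingRate >= 0 && missingRate <= 1,
            "'missingRate' must lie in [0, 1]")
  stopIfNot(is.numeric(jitterSd) && jitterSd >= 0,
            "'jitterSd' must be >= 0")
  structure(list(missingRate = missingRate, jitterSd = jitterSd,
                 blockDelay = blockDelay), class = "CorruptionParams")
}

#' Apply stream corruption to a band-power session
#'
#' Frames are dropped independently at \code{missingRate}; timestamps are
#' shifted by \code{blockDelay} and perturbed by Gaussian jitter; frames
#' are then re-sorted by perturbed timestamp so downstream consumers see
#' an ordered stream.
#'
#' @param session a \linkS4class{BandPowerSession}.
#' @param params corruption parameters from \code{\link{corruptionParams}}.
#' @param seed integer seed (child stream \code{"corruption"}).
#' @return A corrupted \linkS4class{BandPowerSession}.
#' @export
corruptFrames <- function(session, params = corruptionParams(),
                          seed = S4Vectors::metadata(session)$seed) {
  stopIfNot(inherits(params, "CorruptionParams"),
            "'params' must come from corruptionParams()")
  if (is.null(seed)) seed <- 0L
  n <- ncol(session)
  withSeed(childSeed(seed, "corruption"), {
    keep <- runif(n) >= params$missingRate
    ts <- frameTimes(session)[keep] + params$blockDelay +
      rnorm(sum(keep), sd = params$jitterSd)
    ord <- order(ts)
    out <- session[, which(keep)[ord]]
    SummarizedExperiment::colData(out)$timestamp_s <- ts[ord]
    meta <- S4Vectors::metadata(out)
    meta$corruption <- unclass(params)
    S4Vectors::metadata(out) <- meta
    out
  })
}

#' Apply stream corruption to raw samples
#'
#' Same corruption model as \code{\link{corruptFrames}}, applied at the
#' sample level. Because dropped samples break the implicit uniform time
#' grid, the result is returned in explicit long form.
#'
#' @param raw a \linkS4class{RawEeg}.
#' @inheritParams corruptFrames
#' @return A data.frame with columns \code{time_s}, \code{TP9}, \code{AF7},
#'   \code{AF8}, \code{TP10}, sorted by perturbed timestamp.
#' @export
corruptRaw <- function(raw, params = corruptionParams(), seed = raw@seed) {
  stopIfNot(inherits(params, "CorruptionParams"),
            "'params' must come from corruptionParams()")
  n <- nrow(raw@signal)
  withSeed(childSeed(seed, "corruption"), {
    keep <- runif(n) >= params$missingRate
    ts <- (which(keep) / raw@samplingRate) + params$blockDelay +
      rnorm(sum(keep), sd = params$jitterSd)
    ord <- order(ts)
    df <- data.frame(time_s = ts[ord], raw@signal[keep, , drop = FALSE][ord, ])
    colnames(df) <- c("time_s", museElectrodes())
    rownames(df) <- NULL
    df
  })
}
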