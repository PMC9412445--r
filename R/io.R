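#' Write / read a band-power session file
#'
#' The session file is a plain CSV with one row per 100 ms frame and
#' columns \code{timestamp_s}, the 20 feature columns \code{tp9_delta}
#' ... \code{tp10_gamma} (electrode-major, band order delta, theta,
#' alpha, beta, gamma) and \code{label} (\code{internal} /
#' \code{external} / \code{none}). A companion JSON file at
#' \code{<path>.json} carries the metadata: format version, seed, config
#' hash, session plan and generator/extraction parameters. Numbers are
#' written with full precision so a write/read round trip reproduces the
#' session.
#'
#' @param session a \linkS4class{BandPowerSession}.
#' @param path CSV file path; metadata goes to \code{<path>.json}.
#' @return \code{writeSession}: the path, invisibly. \code{readSession}:
#'   the reconstructed \linkS4class{BandPowerSession}.
#' @export
writeSession <- function(session, path) {
  stopIfNot(methods::is(session, "BandPowerSession"),
            "'session' must be a BandPowerSession")
  df <- data.frame(timestamp_s = frameTimes(session),
                   t(SummarizedExperiment::assay(session, "logpower")),
                   label = frameLabels(session))
  colnames(df) <- c("timestamp_s", featureNames(), "label")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- S4Vectors::metadata(session)
  meta$version <- SESSION_FORMAT_VERSION
  if (is.null(meta$config_hash))
    meta$config_hash <- configHash(meta[setdiff(names(meta), "plan")])
  jsonlite::write_json(serializeMeta(meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

serializeMeta <- function(meta) {
  if (!is.null(meta$plan)) {
    meta$plan_seed <- attr(meta$plan, "seed")
    meta$plan <- as.data.frame(meta$plan)
  }
  meta
}

#' @rdname writeSession
#' @param path CSV file path written by \code{writeSession}.
#' @export
readSession <- function(path) {
  stopIfNot(file.exists(path), sprintf("no such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("timestamp_s", featureNames(), "label")
  missing <- setdiff(needed, colnames(df))
  if (length(missing))
    stop("session file is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta <- list()
  metaPath <- paste0(path, ".json")
  if (file.exists(metaPath)) {
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (!is.null(meta$version) &&
        !identical(as.character(meta$version), SESSION_FORMAT_VERSION))
      warning(sprintf("session format version %s (reader expects %s)",
                      meta$version, SESSION_FORMAT_VERSION))
    if (!is.null(meta$plan)) {
      meta$plan <- as.data.frame(meta$plan)
      attr(meta$plan, "seed") <- meta$plan_seed
    }
    if (!is.null(meta$seed)) meta$seed <- as.integer(meta$seed)
  }
  newBandPowerSession(t(as.matrix(df[, featureNames()])), df$timestamp_s,
                      df$label, meta)
}

#' Write / read a trained model as JSON
#'
#' Serializes an \linkS4class{AttentionLda} (weights, bias, class means,
#' pooled covariance, priors, feature order, format version) so a
#' calibration can be reused across sessions.
#'
#' @param model an \linkS4class{AttentionLda}.
#' @param path JSON file path.
#' @return \code{writeModel}: the path, invisibly. \code{readModel}: the
#'   reconstructed \linkS4class{AttentionLda}.
#' @export
writeModel <- function(model, path) {
  stopIfNot(methods::is(model, "AttentionLda"),
            "'model' must be an AttentionLda")
  obj <- list(format = "attention-lda", version = SESSION_FORMAT_VERSION,
              featureOrder = model@featureOrder,
              weights = model@weights, bias = model@bias,
              means = unname(model@means),
              covariance = unname(model@covariance),
              priors = as.list(model@priors), dropped = model@dropped)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  stopIfNot(file.exists(path), sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopIfNot(identical(obj$format, "attention-lda"),
            "not an attention-lda model file")
  means <- matrix(unlist(obj$means), nrow = 2, byrow = !is.matrix(obj$means),
                  dimnames = list(attentionLevels(), obj$featureOrder))
  if (is.matrix(obj$means)) means[] <- obj$means
  d <- length(obj$featureOrder)
  covm <- matrix(unlist(obj$covariance), nrow = d,
                 byrow = !is.matrix(obj$covariance),
                 dimnames = list(obj$featureOrder, obj$featureOrder))
  if (is.matrix(obj$covariance)) covm[] <- obj$covariance
  methods::new("AttentionLda", weights = as.numeric(obj$weights),
               bias = as.numeric(obj$bias), means = means,
               covariance = covm,
               priors = setNames(as.numeric(obj$priors[attentionLevels()]),
                                 attentionLevels()),
               featureOrder = as.character(obj$featureOrder),
               dropped = as.character(obj$dropped))
}

#' Write / read a pause timeline as CSV
#'
#' @param timeline a pause-timeline data.frame (\code{timestamp_s},
#'   \code{paused}, optionally \code{decision}).
#' @param path CSV path; \code{paused} is written as 0/1.
#' @return \code{writeTimeline}: the path, invisibly.
#'   \code{readTimeline}: the timeline data.frame.
#' @export
writeTimeline <- function(timeline, path) {
  df <- data.frame(timestamp_s = sprintf("%.17g", timeline$timestamp_s),
                   paused = as.integer(timeline$paused))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTimeline
#' @export
readTimeline <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("timestamp_s", "paused"), colnames(df))
  if (length(missing))
    stop("timeline file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$paused <- df$paused != 0
  df
}

#' The Mind-Monitor-style stream dialect table
#'
#' Maps the named stream paths of a Mind-Monitor-like OSC source to the
#' package's internal frame fields. The five absolute band-power paths
#' are mandatory; all other subscribed paths (fit indicator, battery,
#' motion, blink, jaw clench) are known but ignored by the band-power
#' pipeline. The table ships as editable CSV
#' (\code{inst/extdata/mind_monitor_dialect.csv}) because the exact path
#' strings vary by bridge version; edit the file or pass a modified
#' table.
#'
#' @return data.frame with columns \code{path}, \code{field},
#'   \code{mandatory}.
#' @export
museDialect <- function() {
  p <- system.file("extdata", "mind_monitor_dialect.csv",
                   package = "attentionBCI")
  read.csv(p, stringsAsFactors = FALSE)
}

#' Convert a long-format stream log into a band-power session
#'
#' Takes a message log with one row per (timestamp, path) carrying the
#' four electrode values, maps band paths through the dialect, and
#' assembles 10 Hz frames from messages sharing a timestamp. Unknown
#' paths are ignored, with one warning reporting how many were skipped.
#' Out-of-order timestamps are re-sorted with a warning.
#'
#' @param log data.frame with columns \code{timestamp_s}, \code{path},
#'   \code{tp9}, \code{af7}, \code{af8}, \code{tp10}.
#' @param dialect a dialect table, default \code{\link{museDialect}}.
#' @return A \linkS4class{BandPowerSession} (labels \code{"none"}).
#' @export
framesFromStreamLog <- function(log, dialect = museDialect()) {
  need <- c("timestamp_s", "path", "tp9", "af7", "af8", "tp10")
  missing <- setdiff(need, colnames(log))
  if (length(missing))
    stop("stream log is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  mand <- dialect$path[dialect$mandatory == 1]
  absent <- setdiff(mand, unique(log$path))
  if (length(absent))
    stop("stream is missing mandatory band path(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  known <- log$path %in% dialect$path
  nUnknownMsgs <- sum(!known)
  if (nUnknownMsgs)
    warning(sprintf("ignored %d message(s) on %d unknown path(s)",
                    nUnknownMsgs, length(unique(log$path[!known]))))
  bandField <- setNames(dialect$field, dialect$path)
  keep <- known & bandField[log$path] %in% bandDefinitions()$band
  log <- log[keep, , drop = FALSE]
  ts <- sort(unique(log$timestamp_s))
  if (is.unsorted(log$timestamp_s)) warning("re-sorted out-of-order timestamps")
  mat <- matrix(NA_real_, nrow = 20, ncol = length(ts),
                dimnames = list(featureNames(), NULL))
  elCols <- c("tp9", "af7", "af8", "tp10")
  for (i in seq_len(nrow(log))) {
    b <- bandField[[log$path[i]]]
    j <- match(log$timestamp_s[i], ts)
    mat[paste(elCols, b, sep = "_"), j] <- as.numeric(log[i, elCols])
  }
  ok <- colSums(is.na(mat)) == 0L
  if (!all(ok)) warning(sprintf("dropped %d incomplete frame(s)", sum(!ok)))
  newBandPowerSession(mat[, ok, drop = FALSE], ts[ok],
                      rep("none", sum(ok)),
                      list(source = "stream-log",
                           version = SESSION_FORMAT_VERSION))
}

#' Replay a session file as a frame stream
#'
#' Delivers the frames of a stored session one by one to a callback, in
#' timestamp order, optionally paced in (scaled) real time -- a desk
#' replacement for a live headset stream.
#'
#' @param path session CSV (see \code{\link{readSession}}).
#' @param callback function called once per frame with a one-row
#'   data.frame (timestamp_s, 20 features, label).
#' @param speed real-time multiplier; \code{Inf} (default) replays as
#'   fast as possible.
#' @return Invisibly, the number of frames delivered.
#' @export
replayStream <- function(path, callback, speed = Inf) {
  session <- readSession(path)
  ts <- frameTimes(session)
  if (is.unsorted(ts)) {
    warning("re-sorted out-of-order frames")
    session <- session[, order(ts)]
    ts <- frameTimes(session)
  }
  df <- data.frame(timestamp_s = ts,
                   t(SummarizedExperiment::assay(session, "logpower")),
                   label = frameLabels(session))
  colnames(df) <- c("timestamp_s", featureNames(), "label")
  prev <- NULL
  for (i in seq_len(nrow(df))) {
    if (is.finite(speed) && !is.null(prev))
      Sys.sleep(max(0, (df$timestamp_s[i] - prev) / speed))
    prev <- df$timestamp_s[i]
    callback(df[i, , drop = FALSE])
  }
  invisible(nrow(df))
}

#' Write / read a raw EEG segment as CSV
#'
#' Long-format raw file: \code{time_s}, \code{TP9}, \code{AF7},
#' \code{AF8}, \code{TP10}; sampling rate and plan go to
#' \code{<path>.json}.
#'
#' @param raw a \linkS4class{RawEeg}.
#' @param path CSV path.
#' @return \code{writeRaw}: the path, invisibly. \code{readRaw}: the
#'   \linkS4class{RawEeg}.
#' @export
writeRaw <- function(raw, path) {
  stopIfNot(methods::is(raw, "RawEeg"), "'raw' must be a RawEeg")
  df <- data.frame(time_s = sprintf("%.17g",
                                    seq_len(nrow(raw@signal)) / raw@samplingRate))
  for (ch in museElectrodes())
    df[[ch]] <- sprintf("%.17g", raw@signal[, ch])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(samplingRate = raw@samplingRate, seed = raw@seed,
               plan = raw@plan, plan_seed = attr(raw@plan, "seed"),
               version = SESSION_FORMAT_VERSION)
  meta$config_hash <- configHash(meta[c("samplingRate", "seed")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRaw
#' @export
readRaw <- function(path) {
  stopIfNot(file.exists(path), sprintf("no such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("time_s", museElectrodes()), colnames(df))
  if (length(missing))
    stop("raw file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  metaPath <- paste0(path, ".json")
  stopIfNot(file.exists(metaPath),
            "raw file has no metadata JSON (sampling rate unknown)")
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  plan <- if (!is.null(meta$plan)) {
    p <- as.data.frame(meta$plan)
    attr(p, "seed") <- meta$plan_seed
    p
  } else data.frame()
  sig <- as.matrix(df[, museElectrodes()])
  colnames(sig) <- museElectrodes()
  methods::new("RawEeg", signal = sig, samplingRate = meta$samplingRate,
               plan = plan,
               seed = if (is.null(meta$seed)) NA_integer_
                      else as.integer(meta$seed))
}
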