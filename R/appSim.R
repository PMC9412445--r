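#' Update-scheduler parameters of the simulated adaptive application
#'
#' The adaptive application this package emulates refreshes its display
#' (AR text stickers) on a restart-per-cycle timer: each refresh takes
#' between 0.3 and 3 s, and a new interval is drawn (uniformly) when the
#' previous update fires.
#'
#' @param intervalS length-2 numeric, lower/upper bound of the update
#'   interval in seconds (default \code{c(0.3, 3.0)}).
#' @param seed RNG seed for the interval draws (child stream
#'   \code{"updater"}).
#' @return A validated list of class \code{"UpdaterParams"}.
#' @export
updaterParams <- function(intervalS = c(0.3, 3.0), seed = 0) {
  stopIfNot(is.numeric(intervalS) && length(intervalS) == 2 &&
              intervalS[1] > 0 && intervalS[1] <= intervalS[2],
            "'intervalS' must be 0 < low <= high")
  structure(list(intervalS = intervalS, seed = as.integer(seed)),
            class = "UpdaterParams")
}

#' Closed-loop simulation of the attention-adaptive application
#'
#' Runs the whole online chain on a band-power session: the trained
#' discriminant predicts the attentional state of every 100 ms frame, the
#' pause decider votes over the last 4 s, and a simulated application
#' schedules update events at its 0.3--3 s cadence, suspending them while
#' paused. Updates that come due during a pause are deferred, not
#' dropped: they fire at the moment the pause ends.
#'
#' @param session a \linkS4class{BandPowerSession} whose feature order
#'   matches the model.
#' @param model an \linkS4class{AttentionLda}.
#' @param decider a \code{\link{deciderConfig}}.
#' @param updater an \code{\link{updaterParams}}.
#' @param forceState for testing: \code{"none"} (default) uses the
#'   decider; \code{"paused"} / \code{"unpaused"} forces the post-warm-up
#'   pause state.
#' @return A list with \code{timeline} (per-frame pause decisions, see
#'   \code{\link{decideBatch}}), \code{events} (data.frame
#'   \code{timestamp_s}, \code{kind} in \code{update}, \code{pause_start},
#'   \code{pause_end}), \code{predictions} (per-frame state/score) and
#'   \code{duration_s}.
#' @export
#' @examples
#' sess <- synthesizeBandPower(makeSessionPlan(1, 20, 20, seed = 5))
#' model <- trainAttentionLda(sess)
#' sim <- runLoop(sess, model)
#' head(sim$events)
runLoop <- function(session, model, decider = deciderConfig(),
                    updater = updaterParams(),
                    forceState = c("none", "paused", "unpaused")) {
  forceState <- match.arg(forceState)
  feats <- featureMatrix(session)
  if (!identical(colnames(feats), model@featureOrder))
    stop("feature order of the session does not match the model",
         call. = FALSE)
  pred <- predict(model, feats)
  times <- frameTimes(session)
  timeline <- decideBatch(pred$state, decider, times = times)
  if (forceState != "none") {
    warm <- timeline$decision == "warming-up"
    timeline$paused <- !warm & (forceState == "paused")
    timeline$decision <- ifelse(warm, "warming-up",
                                ifelse(timeline$paused, "paused", "unpaused"))
  }
  duration <- max(times)
  framePeriod <- 1 / FRAME_RATE_HZ

  # piecewise-constant pause state: decision at timestamp t governs
  # [t, t + 0.1); before the first decision the app runs unpaused
  stateStart <- c(0, timeline$timestamp_s)
  stateVal <- c(FALSE, timeline$paused)
  pausedAt <- function(t) {
    i <- findInterval(t, stateStart)
    stateVal[max(i, 1L)]
  }
  # end of the paused run containing time t (t itself paused)
  pauseEndAfter <- function(t) {
    i <- findInterval(t, stateStart)
    while (i < length(stateVal) && stateVal[i]) i <- i + 1L
    if (stateVal[min(i, length(stateVal))]) duration  # paused to the end
    else stateStart[i]
  }

  evT <- numeric(0); evK <- character(0)
  r <- rle(timeline$paused)
  runEnd <- cumsum(r$lengths)
  runStart <- c(1L, head(runEnd, -1L) + 1L)
  for (j in which(r$values)) {
    evT <- c(evT, timeline$timestamp_s[runStart[j]])
    evK <- c(evK, "pause_start")
    endT <- if (runEnd[j] < nrow(timeline))
      timeline$timestamp_s[runEnd[j] + 1L]
    else timeline$timestamp_s[runEnd[j]] + framePeriod
    evT <- c(evT, min(endT, duration)); evK <- c(evK, "pause_end")
  }

  withSeed(childSeed(updater$seed, "updater"), {
    nextUp <- runif(1, updater$intervalS[1], updater$intervalS[2])
    while (nextUp <= duration) {
      fireAt <- nextUp
      if (pausedAt(fireAt)) {
        fireAt <- pauseEndAfter(fireAt)   # deferred to pause end
        if (fireAt >= duration) break
      }
      evT <- c(evT, fireAt); evK <- c(evK, "update")
      nextUp <- fireAt + runif(1, updater$intervalS[1], updater$intervalS[2])
    }
  })

  ord <- order(evT, match(evK, c("pause_end", "update", "pause_start")))
  events <- data.frame(timestamp_s = evT[ord], kind = evK[ord],
                       stringsAsFactors = FALSE)
  list(timeline = timeline, events = events, predictions = pred,
       duration_s = duration)
}

#' Summarize a simulated event log
#'
#' @param events event log data.frame (\code{timestamp_s}, \code{kind})
#'   as produced by \code{\link{runLoop}}.
#' @param duration_s total session duration in seconds.
#' @return A list: \code{updateCount}, \code{pausedTime_s},
#'   \code{pausedFraction}, \code{meanUpdateGap_s} (NA with < 2 updates).
#' @export
summarizeEvents <- function(events, duration_s) {
  stopIfNot(is.data.frame(events) &&
              all(c("timestamp_s", "kind") %in% names(events)),
            "'events' must have columns timestamp_s and kind")
  ups <- events$timestamp_s[events$kind == "update"]
  ps <- events$timestamp_s[events$kind == "pause_start"]
  pe <- events$timestamp_s[events$kind == "pause_end"]
  stopIfNot(length(ps) == length(pe),
            "pause_start/pause_end events must alternate")
  pausedTime <- sum(pmin(pe, duration_s) - ps)
  list(updateCount = length(ups),
       pausedTime_s = pausedTime,
       pausedFraction = if (duration_s > 0) pausedTime / duration_s else 0,
       meanUpdateGap_s = if (length(ups) >= 2) mean(diff(ups)) else NA_real_)
}
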