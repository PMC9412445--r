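#' Pause-decision configuration
#'
#' The pause rule compiles the last \code{n} attention predictions
#' (4 s at 10 Hz with the default n = 40) and pauses the application's
#' updates iff at least \code{threshold} of them are \emph{internal}
#' (>= ceiling(threshold * n), i.e. >= 24 of 40 at defaults). The 60\%
#' threshold deliberately biases the system toward \emph{not} pausing:
#' wrongly pausing during external attention is considered more harmful
#' than missing a pause during internal attention.
#'
#' @param n number of predictions in the vote window (default 40).
#' @param threshold internal fraction required to pause, in (0, 1]
#'   (default 0.6); "at least" is inclusive.
#' @param mode \code{"sliding"} (default) re-evaluates the vote on every
#'   new prediction; \code{"block"} decides once per disjoint n-prediction
#'   block and holds the decision in between.
#' @param maxPauseS optional cap on continuous pause length in seconds
#'   (default \code{Inf}, i.e. uncapped, reproducing the uncapped behavior
#'   in which pauses over 30 s can occur).
#' @return A validated list of class \code{"DeciderConfig"}. The derived
#'   vote count is exposed as \code{$minInternal}.
#' @export
#' @examples
#' deciderConfig()$minInternal   # 24
deciderConfig <- function(n = 40L, threshold = 0.6,
                          mode = c("sliding", "block"), maxPauseS = Inf) {
  stopIfNot(is.numeric(n) && n >= 1 && n == round(n),
            "'n' must be a count >= 1")
  stopIfNot(is.numeric(threshold) && threshold > 0 && threshold <= 1,
            "'threshold' must lie in (0, 1]")
  mode <- match.arg(mode)
  structure(list(n = as.integer(n), threshold = threshold, mode = mode,
                 maxPauseS = maxPauseS,
                 minInternal = as.integer(ceiling(threshold * n))),
            class = "DeciderConfig")
}

#' Streaming pause decider
#'
#' A stateful decider holding a ring buffer of the last \code{n}
#' predictions. Until the buffer fills (the first n - 1 predictions) it
#' reports \code{"warming-up"} and the timeline records unpaused,
#' consistent with the bias toward not pausing.
#'
#' @param config a \code{\link{deciderConfig}} (sliding mode).
#' @return An object of class \code{"PauseDecider"}: call
#'   \code{d$update(prediction)} with \code{"internal"} or
#'   \code{"external"}; it returns \code{"paused"}, \code{"unpaused"} or
#'   \code{"warming-up"}. \code{d$reset()} clears the state.
#' @export
#' @examples
#' d <- newPauseDecider()
#' d$update("internal")   # "warming-up"
newPauseDecider <- function(config = deciderConfig()) {
  stopIfNot(inherits(config, "DeciderConfig"),
            "'config' must come from deciderConfig()")
  buf <- integer(0)
  update <- function(prediction) {
    stopIfNot(prediction %in% attentionLevels(),
              "prediction must be 'internal' or 'external'")
    buf <<- c(buf, as.integer(prediction == "internal"))
    if (length(buf) > config$n) buf <<- buf[-1L]
    if (length(buf) < config$n) return("warming-up")
    if (sum(buf) >= config$minInternal) "paused" else "unpaused"
  }
  reset <- function() buf <<- integer(0)
  structure(list(update = update, reset = reset, config = config),
            class = "PauseDecider")
}

#' Offline pause timeline from a prediction sequence
#'
#' Replays the streaming decision rule over a whole prediction sequence.
#' In sliding mode (default) the vote over the last n predictions is
#' re-evaluated at every prediction; in block mode one decision is taken
#' per disjoint n-prediction block and held until the next block
#' completes. Warm-up decisions are recorded as unpaused.
#'
#' @param predictions character vector of \code{"internal"} /
#'   \code{"external"} predictions (or a factor), in stream order.
#' @param config a \code{\link{deciderConfig}}.
#' @param times optional per-prediction timestamps in seconds; defaults
#'   to a 10 Hz grid starting at 0.1 s.
#' @return A pause timeline: data.frame with columns \code{timestamp_s},
#'   \code{paused} (logical) and \code{decision}
#'   (\code{"warming-up"} / \code{"paused"} / \code{"unpaused"}), one row
#'   per prediction.
#' @export
#' @examples
#' p <- rep(c("internal", "external"), 50)
#' tl <- decideBatch(p)
#' any(tl$paused)   # alternating stream never reaches 60%
decideBatch <- function(predictions, config = deciderConfig(),
                        times = NULL) {
  stopIfNot(inherits(config, "DeciderConfig"),
            "'config' must come from deciderConfig()")
  predictions <- as.character(predictions)
  stopIfNot(all(predictions %in% attentionLevels()),
            "predictions must be 'internal' or 'external'")
  m <- length(predictions)
  if (is.null(times)) times <- seq_len(m) / FRAME_RATE_HZ
  stopIfNot(length(times) == m, "'times' must match 'predictions'")
  ind <- cumsum(predictions == "internal")
  n <- config$n
  decision <- rep("warming-up", m)
  paused <- logical(m)
  if (m >= n) {
    idx <- n:m
    cnt <- ind[idx] - c(0, ind)[idx - n + 1L]
    if (config$mode == "sliding") {
      paused[idx] <- cnt >= config$minInternal
      decision[idx] <- ifelse(paused[idx], "paused", "unpaused")
    } else {
      blockEnds <- idx[(idx %% n) == 0L]
      cntB <- cnt[match(blockEnds, idx)]
      state <- FALSE
      for (j in seq_along(blockEnds)) {
        state <- cntB[j] >= config$minInternal
        from <- blockEnds[j]
        to <- if (j < length(blockEnds)) blockEnds[j + 1L] - 1L else m
        paused[from:to] <- state
        decision[from:to] <- if (state) "paused" else "unpaused"
      }
    }
  }
  if (is.finite(config$maxPauseS)) {
    cap <- max(1L, floor(config$maxPauseS * FRAME_RATE_HZ))
    r <- rle(paused)
    pos <- cumsum(c(1L, head(r$lengths, -1L)))
    for (j in which(r$values & r$lengths > cap)) {
      over <- (pos[j] + cap):(pos[j] + r$lengths[j] - 1L)
      paused[over] <- FALSE
      decision[over] <- "unpaused"
    }
  }
  data.frame(timestamp_s = times, paused = paused, decision = decision,
             stringsAsFactors = FALSE)
}
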