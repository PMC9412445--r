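#' Assemble a trial record for offline evaluation
#'
#' A trial is one reading phase (ground truth: external attention)
#' followed by one task phase (ground truth: internal attention), together
#' with the per-frame predictions made over both. The \code{rereading}
#' flag marks trials in which the participant is believed to have looked
#' back at the text while solving the task ("thinking and rereading"),
#' which makes the nominal internal ground truth partly wrong; such trials
#' are eligible for the 5-bin correction of \code{\link{binCorrect}}.
#'
#' @param times per-frame timestamps in seconds.
#' @param predicted per-frame predicted states (\code{"internal"} /
#'   \code{"external"}).
#' @param reading length-2 numeric, start/end of the reading interval.
#' @param task length-2 numeric, start/end of the task interval; must not
#'   overlap the reading interval and must come after it.
#' @param rereading logical flag (default FALSE). The package does not
#'   guess this: set it from task metadata, or see
#'   \code{\link{flagRereading}} for an explicit heuristic.
#' @param id optional trial identifier.
#' @return A list of class \code{"attnTrial"} with the per-phase frame
#'   indices resolved. Frames are assigned to a phase when their
#'   timestamp t lies in (start, end] (windows are [t-1, t)).
#' @export
makeTrial <- function(times, predicted, reading, task, rereading = FALSE,
                      id = NA) {
  stopIfNot(length(times) == length(predicted),
            "'times' and 'predicted' must align")
  stopIfNot(length(reading) == 2 && length(task) == 2 &&
              reading[1] < reading[2] && task[1] < task[2],
            "intervals must be (start, end) with start < end")
  stopIfNot(task[1] >= reading[2],
            "reading must precede the task, without overlap")
  inReading <- times > reading[1] & times <= reading[2]
  inTask <- times > task[1] & times <= task[2]
  stopIfNot(any(inReading) && any(inTask),
            "predictions must cover both intervals")
  structure(list(id = id, times = times,
                 predicted = as.character(predicted),
                 reading = reading, task = task,
                 inReading = inReading, inTask = inTask,
                 rereading = isTRUE(rereading)),
            class = "attnTrial")
}

#' Per-phase classification accuracy of a trial
#'
#' Ground truth is phase-derived: every reading frame is external, every
#' task frame internal. Accuracy is the fraction of frames whose
#' prediction matches that label, reported for the reading phase, the
#' task phase, and both pooled.
#'
#' @param trial an \code{\link{makeTrial}} record.
#' @return Named numeric: \code{reading}, \code{task}, \code{overall}.
#' @export
trialAccuracy <- function(trial) {
  stopIfNot(inherits(trial, "attnTrial"), "'trial' must come from makeTrial()")
  rAcc <- mean(trial$predicted[trial$inReading] == "external")
  tAcc <- mean(trial$predicted[trial$inTask] == "internal")
  nR <- sum(trial$inReading); nT <- sum(trial$inTask)
  c(reading = rAcc, task = tAcc,
    overall = (rAcc * nR + tAcc * nT) / (nR + nT))
}

#' Bin-corrected task accuracy for rereading trials
#'
#' For trials flagged as "thinking and rereading", the nominal internal
#' ground truth during the task is partly wrong. The task phase is split
#' into \code{nBins} equal-duration bins; bins in which the predicted
#' external fraction exceeds \code{threshold} are treated as rereading
#' episodes and excluded, and task accuracy (vs. the internal label) is
#' recomputed over the remaining frames. Unflagged trials are returned
#' unchanged with no bins excluded.
#'
#' @param trial an \code{\link{makeTrial}} record.
#' @param nBins number of bins (default 5).
#' @param threshold external-predicted fraction above which a bin is
#'   excluded (default 0.5; the identification rule's exact cut-off is a
#'   package choice, exposed here).
#' @return A list: \code{accuracy} (corrected task accuracy; NA with a
#'   warning if every bin is excluded), \code{excluded} (logical per
#'   bin), \code{binAccuracy} (per-bin internal fraction).
#' @export
binCorrect <- function(trial, nBins = 5, threshold = 0.5) {
  stopIfNot(inherits(trial, "attnTrial"), "'trial' must come from makeTrial()")
  stopIfNot(nBins >= 1, "'nBins' must be >= 1")
  tt <- trial$times[trial$inTask]
  pp <- trial$predicted[trial$inTask]
  stopIfNot(length(tt) >= nBins, "task phase must have at least nBins frames")
  edges <- seq(trial$task[1], trial$task[2], length.out = nBins + 1)
  bin <- pmin(pmax(findInterval(tt, edges, left.open = TRUE), 1L), nBins)
  intFrac <- vapply(seq_len(nBins),
                    function(b) mean(pp[bin == b] == "internal"), numeric(1))
  if (trial$rereading) {
    excluded <- (1 - intFrac) > threshold
  } else {
    excluded <- rep(FALSE, nBins)
  }
  keep <- !excluded[bin]
  if (!any(keep)) {
    warning("all bins excluded; corrected accuracy undefined")
    acc <- NA_real_
  } else {
    acc <- mean(pp[keep] == "internal")
  }
  list(accuracy = acc, excluded = excluded, binAccuracy = intFrac)
}

#' Heuristic rereading flag from task durations
#'
#' An optional, explicit heuristic (off unless called): flag trials whose
#' task-solving time exceeds the median task time across trials, the
#' observable correlate of thinking-plus-rereading behavior. The study
#' rule this approximates is not published; prefer explicit flags when
#' available.
#'
#' @param taskDurations numeric vector of task durations in seconds.
#' @return Logical vector, TRUE where duration > median.
#' @export
flagRereading <- function(taskDurations) {
  taskDurations > stats::median(taskDurations)
}

#' Segment a pause timeline into constant-state blocks
#'
#' Each maximal run of constant pause state is one block; its duration is
#' the run length times the 100 ms frame period. Blocks are categorized
#' by length with the configured edges: [0, 3), [3, 10), [10, 30) and
#' [30, Inf) seconds by default.
#'
#' @param timeline a pause timeline (data.frame with \code{timestamp_s}
#'   and logical \code{paused}), e.g. from \code{\link{decideBatch}}.
#' @param edges strictly increasing category edges in seconds
#'   (default \code{c(3, 10, 30)}).
#' @return A data.frame with one row per block: \code{start_s},
#'   \code{end_s}, \code{duration_s}, \code{paused}, \code{category}
#'   (factor, e.g. \code{"<3s"}, \code{"3-10s"}, \code{"10-30s"},
#'   \code{">30s"}).
#' @export
#' @examples
#' tl <- data.frame(timestamp_s = (1:600) / 10,
#'                  paused = rep(c(FALSE, TRUE), each = 300))
#' segmentBlocks(tl)
segmentBlocks <- function(timeline, edges = c(3, 10, 30)) {
  stopIfNot(is.data.frame(timeline) && nrow(timeline) > 0 &&
              all(c("timestamp_s", "paused") %in% names(timeline)),
            "'timeline' must be a non-empty data.frame with timestamp_s, paused")
  stopIfNot(all(diff(edges) > 0), "'edges' must be strictly increasing")
  r <- rle(timeline$paused)
  endIdx <- cumsum(r$lengths)
  startIdx <- c(1L, head(endIdx, -1L) + 1L)
  period <- 1 / FRAME_RATE_HZ
  start <- timeline$timestamp_s[startIdx]
  dur <- r$lengths * period
  labs <- blockCategoryLabels(edges)
  cat <- cut(dur, breaks = c(0, edges, Inf), labels = labs, right = FALSE)
  data.frame(start_s = start, end_s = start + dur, duration_s = dur,
             paused = r$values, category = cat)
}

blockCategoryLabels <- function(edges = c(3, 10, 30)) {
  c(sprintf("<%gs", edges[1]),
    sprintf("%g-%gs", head(edges, -1L), tail(edges, -1L)),
    sprintf(">%gs", tail(edges, 1L)))
}

#' Equal-participant-weight block-length shares
#'
#' Computes, per participant, the distribution of their blocks over the
#' length categories, then averages the distributions with equal weight
#' per participant -- so a participant with many short blocks does not
#' dominate one with a single long block.
#'
#' @param blocksList list with one \code{\link{segmentBlocks}} data.frame
#'   per participant.
#' @param paused if not NULL (default TRUE), restrict to blocks with this
#'   pause state before computing shares.
#' @param edges category edges, as in \code{\link{segmentBlocks}}.
#' @return Named numeric vector of category shares, summing to 1 (all NA
#'   if no participant contributes any block).
#' @export
blockShare <- function(blocksList, paused = TRUE, edges = c(3, 10, 30)) {
  stopIfNot(is.list(blocksList) && length(blocksList) >= 1,
            "need at least one participant")
  labs <- blockCategoryLabels(edges)
  dists <- lapply(blocksList, function(b) {
    if (!is.null(paused)) b <- b[b$paused == paused, , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    tab <- table(factor(as.character(b$category), levels = labs))
    as.numeric(tab) / sum(tab)
  })
  dists <- dists[!vapply(dists, is.null, logical(1))]
  if (length(dists) == 0L) return(setNames(rep(NA_real_, length(labs)), labs))
  setNames(Reduce(`+`, dists) / length(dists), labs)
}

#' Percentage of time paused within an interval
#'
#' @param timeline a pause timeline (see \code{\link{segmentBlocks}}).
#' @param interval length-2 numeric (start, end] in seconds; default the
#'   whole timeline.
#' @return Percentage in [0, 100]: 100 x paused frames / total frames in
#'   the interval.
#' @export
#' @examples
#' tl <- data.frame(timestamp_s = (1:1000) / 10,
#'                  paused = rep(c(TRUE, FALSE), c(170, 830)))
#' pausedPercentage(tl)   # 17
pausedPercentage <- function(timeline, interval = NULL) {
  stopIfNot(is.data.frame(timeline) && nrow(timeline) > 0,
            "'timeline' must be a non-empty data.frame")
  if (is.null(interval))
    interval <- c(min(timeline$timestamp_s) - 1 / FRAME_RATE_HZ,
                  max(timeline$timestamp_s))
  sel <- timeline$timestamp_s > interval[1] &
    timeline$timestamp_s <= interval[2]
  stopIfNot(any(sel), "interval contains no timeline frames")
  100 * mean(timeline$paused[sel])
}

#' Correlation between two session-level measures
#'
#' Product-moment (Pearson) correlation with its two-sided t-test
#' p-value, as used for, e.g., relating pause time during reading to
#' task-solving time. Spearman's rank correlation is available via
#' \code{method}.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return A list: \code{r} (estimate), \code{p} (two-sided p-value),
#'   \code{n}, \code{method}.
#' @export
#' @examples
#' attentionCor(1:10, 2 * (1:10) + 1)$r   # 1
attentionCor <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopIfNot(length(x) == length(y), "'x' and 'y' must have equal length")
  stopIfNot(length(x) >= 3, "need at least 3 observations")
  stopIfNot(sd(x) > 0 && sd(y) > 0, "inputs must not be constant")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}
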