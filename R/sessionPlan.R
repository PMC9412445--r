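#' Build a calibration/evaluation session plan
#'
#' A session is a sequence of trials, each consisting of a reading phase
#' (externally directed attention) followed by a task phase (internally
#' directed attention, e.g. answering a question about the text). The
#' standard calibration session of the system this package models is four
#' such trials of 50 s + 50 s, i.e. eight parts and 400 s of training data.
#'
#' @param nTrials number of trials (>= 1).
#' @param readingS duration of each reading phase in seconds (> 0).
#' @param taskS duration of each task phase in seconds (> 0).
#' @param seed integer seed stored in the plan; all downstream generators
#'   derive named child streams from it, so a plan pins down an entire
#'   reproducible session.
#' @return A data.frame with one row per phase and columns \code{phase}
#'   (index), \code{trial}, \code{state} (\code{"external"} /
#'   \code{"internal"}), \code{start_s}, \code{end_s}, \code{duration_s};
#'   the seed is attached as \code{attr(plan, "seed")}.
#' @export
#' @examples
#' plan <- makeSessionPlan(4, 50, 50, seed = 1)
#' sum(plan$duration_s)   # 400 s
#' nrow(plan)             # 8 phases
makeSessionPlan <- function(nTrials = 4, readingS = 50, taskS = 50,
                            seed = 0) {
  stopIfNot(is.numeric(nTrials) && length(nTrials) == 1 && nTrials >= 1 &&
              nTrials == round(nTrials), "'nTrials' must be a count >= 1")
  stopIfNot(is.numeric(readingS) && length(readingS) == 1 && readingS > 0,
            "'readingS' must be a positive duration in seconds")
  stopIfNot(is.numeric(taskS) && length(taskS) == 1 && taskS > 0,
            "'taskS' must be a positive duration in seconds")
  nTrials <- as.integer(nTrials)
  durations <- rep(c(readingS, taskS), nTrials)
  ends <- cumsum(durations)
  plan <- data.frame(
    phase = seq_len(2L * nTrials),
    trial = rep(seq_len(nTrials), each = 2L),
    state = rep(attentionLevels(), nTrials),
    start_s = c(0, head(ends, -1L)),
    end_s = ends,
    duration_s = durations,
    stringsAsFactors = FALSE
  )
  attr(plan, "seed") <- as.integer(seed)
  plan
}

#' Session plan with rereading episodes inside task phases
#'
#' Like \code{\link{makeSessionPlan}}, but in flagged trials the task
#' phase contains a centered rereading episode: the participant looks
#' back at the text while solving the task, so attention turns external
#' in the middle of a nominally internal phase. This reproduces the
#' ground-truth imperfection that the 5-bin correction
#' (\code{\link{binCorrect}}) addresses: a trial-level evaluation that
#' labels the whole task phase internal under-reports accuracy there.
#'
#' @inheritParams makeSessionPlan
#' @param rereadS duration of the external episode inside each flagged
#'   trial's task phase, in seconds (> 0, < taskS).
#' @param rereadTrials indices of the flagged trials (default: every
#'   second trial).
#' @return A plan data.frame as in \code{\link{makeSessionPlan}}, with an
#'   extra logical column \code{reread} marking the injected episodes,
#'   and \code{attr(plan, "rereadTrials")}.
#' @export
#' @examples
#' plan <- makeRereadingPlan(4, 50, 50, rereadS = 15, seed = 2)
#' subset(plan, trial == 2)
makeRereadingPlan <- function(nTrials = 4, readingS = 50, taskS = 50,
                              rereadS = 15,
                              rereadTrials = seq(2, nTrials, by = 2),
                              seed = 0) {
  stopIfNot(rereadS > 0 && rereadS < taskS,
            "'rereadS' must be positive and shorter than the task phase")
  base <- makeSessionPlan(nTrials, readingS, taskS, seed)
  rows <- list()
  for (tr in seq_len(nTrials)) {
    ph <- base[base$trial == tr, ]
    rows[[length(rows) + 1L]] <- cbind(ph[1L, ], reread = FALSE)
    task <- ph[2L, ]
    if (tr %in% rereadTrials) {
      half <- (task$duration_s - rereadS) / 2
      st <- task$start_s
      seg <- data.frame(
        phase = NA, trial = tr,
        state = c("internal", "external", "internal"),
        start_s = st + c(0, half, half + rereadS),
        end_s = st + c(half, half + rereadS, task$duration_s),
        duration_s = c(half, rereadS, half),
        reread = c(FALSE, TRUE, FALSE))
      rows[[length(rows) + 1L]] <- seg
    } else {
      rows[[length(rows) + 1L]] <- cbind(task, reread = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  plan$phase <- seq_len(nrow(plan))
  rownames(plan) <- NULL
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "rereadTrials") <- as.integer(rereadTrials)
  plan
}

# total duration of a plan in seconds
planDuration <- function(plan) sum(plan$duration_s)

# Majority-coverage label for an analysis window [t - win, t), clipped to
# the plan's extent. Ties (exactly half the covered time in each state) go
# to "external", consistent with the decision rule's bias toward not
# pausing. Windows with no overlap at all get "none".
labelForWindow <- function(t, plan, win = FRAME_WINDOW_S) {
  lo <- pmax(t - win, 0)
  hi <- t
  intCov <- extCov <- numeric(length(t))
  for (i in seq_len(nrow(plan))) {
    ov <- pmax(0, pmin(hi, plan$end_s[i]) - pmax(lo, plan$start_s[i]))
    if (plan$state[i] == "internal") intCov <- intCov + ov
    else extCov <- extCov + ov
  }
  out <- rep("none", length(t))
  covered <- (intCov + extCov) > 0
  # near-equal coverage counts as a tie (guards float drift on exact
  # half-window boundaries), and ties go to external
  out[covered] <- ifelse(intCov[covered] > extCov[covered] + 1e-9,
                         "internal", "external")
  out
}
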