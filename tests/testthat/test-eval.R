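mkTrial <- function(pred, reading = c(0, 10), task = c(10, 20),
                    rereading = FALSE) {
  n <- length(pred)
  makeTrial((1:n) / 10, pred, reading, task, rereading = rereading)
}

test_that("per-phase accuracy counts matches against phase-derived labels", {
  allRight <- c(rep("external", 100), rep("internal", 100))
  expect_equal(unname(trialAccuracy(mkTrial(allRight))), c(1, 1, 1))
  readWrong <- c(rep("internal", 100), rep("internal", 100))
  acc <- trialAccuracy(mkTrial(readWrong))
  expect_equal(unname(acc), c(0, 1, 0.5))
  # random trials vs a direct recount
  withr::with_seed(21, {
    for (rep in 1:10) {
      pred <- sample(c("internal", "external"), 200, replace = TRUE)
      tr <- mkTrial(pred)
      want <- c(mean(pred[1:100] == "external"),
                mean(pred[101:200] == "internal"))
      got <- trialAccuracy(tr)
      expect_equal(unname(got[1:2]), want)
      expect_equal(unname(got[3]), mean(want))
    }
  })
})

test_that("trial records validate their intervals", {
  expect_error(makeTrial(1:10 / 10, rep("internal", 10), c(0, 0.5), c(0.4, 1)),
               "precede")
  expect_error(makeTrial(1:10 / 10, rep("internal", 10), c(0.5, 0.2), c(0.5, 1)),
               "start < end")
  expect_error(makeTrial(1:5 / 10, rep("internal", 5), c(0, 0.2), c(10, 20)),
               "cover")
})

test_that("bin correction excludes external-dominated bins in flagged trials only", {
  # middle task bin fully external-predicted, others internal
  pred <- c(rep("external", 100),
            rep("internal", 40), rep("external", 20), rep("internal", 40))
  flagged <- mkTrial(pred, rereading = TRUE)
  out <- binCorrect(flagged, nBins = 5)
  expect_equal(out$excluded, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$accuracy, 1.0)
  unflagged <- mkTrial(pred, rereading = FALSE)
  out2 <- binCorrect(unflagged, nBins = 5)
  expect_false(any(out2$excluded))
  expect_equal(out2$accuracy, 0.8)    # uncorrected task accuracy
  # uniform internal predictions: nothing excluded, accuracy unchanged
  uni <- mkTrial(c(rep("external", 100), rep("internal", 100)),
                 rereading = TRUE)
  out3 <- binCorrect(uni)
  expect_false(any(out3$excluded))
  expect_equal(out3$accuracy, 1.0)
})

test_that("task bins partition the task frames", {
  pred <- rep(c("internal", "external"), 100)
  tr <- mkTrial(pred)
  tt <- tr$times[tr$inTask]
  edges <- seq(10, 20, length.out = 6)
  bin <- pmin(pmax(findInterval(tt, edges, left.open = TRUE), 1L), 5L)
  expect_equal(sum(table(bin)), length(tt))       # union covers all frames
  expect_equal(as.vector(table(bin)), rep(20, 5)) # pairwise disjoint, equal
})

test_that("all-excluded bins yield a missing corrected accuracy with warning", {
  pred <- c(rep("external", 100), rep("external", 100))
  tr <- mkTrial(pred, rereading = TRUE)
  expect_warning(out <- binCorrect(tr), "all bins excluded")
  expect_true(is.na(out$accuracy))
  expect_true(all(out$excluded))
})

test_that("the rereading heuristic flags above-median task durations", {
  expect_equal(flagRereading(c(30, 60, 45, 80)),
               c(FALSE, TRUE, FALSE, TRUE))
})

test_that("block segmentation equals a run-length oracle on random timelines", {
  withr::with_seed(22, {
    for (rep in 1:200) {
      n <- sample(5:200, 1)
      paused <- sample(c(TRUE, FALSE), n, replace = TRUE)
      tl <- data.frame(timestamp_s = (1:n) / 10, paused = paused)
      blocks <- segmentBlocks(tl)
      want <- oracleBlocks(paused)
      expect_equal(nrow(blocks), nrow(want))
      expect_equal(blocks$duration_s, want$len / 10)
      expect_equal(blocks$paused, want$paused)
      # durations add to the timeline's span exactly
      expect_equal(sum(blocks$duration_s), n / 10)
      # round trip: re-expanding the blocks reproduces the timeline
      rebuilt <- rep(blocks$paused, blocks$duration_s * 10)
      expect_equal(rebuilt, paused)
    }
  })
})

test_that("block length categories use the 3/10/30 s edges", {
  tl <- data.frame(timestamp_s = (1:400) / 10, paused = rep(TRUE, 400))
  b <- segmentBlocks(tl)
  expect_equal(nrow(b), 1)
  expect_equal(as.character(b$category), ">30s")
  alt <- data.frame(timestamp_s = (1:100) / 10,
                    paused = rep(c(TRUE, FALSE), 50))
  ba <- segmentBlocks(alt)
  expect_true(all(ba$duration_s == 0.1))
  expect_true(all(as.character(ba$category) == "<3s"))
  mix <- data.frame(timestamp_s = (1:200) / 10,
                    paused = rep(c(TRUE, FALSE, TRUE, FALSE),
                                 c(25, 45, 110, 20)))
  expect_equal(as.character(segmentBlocks(mix)$category),
               c("<3s", "3-10s", "10-30s", "<3s"))
})

test_that("block shares weight participants equally and are duplication-invariant", {
  short <- data.frame(duration_s = rep(1, 10), paused = TRUE,
                      category = factor(rep("<3s", 10),
                                        levels = c("<3s", "3-10s", "10-30s", ">30s")))
  long <- data.frame(duration_s = 40, paused = TRUE,
                     category = factor(">30s",
                                       levels = c("<3s", "3-10s", "10-30s", ">30s")))
  sh <- blockShare(list(short, long))
  expect_equal(unname(sh), c(0.5, 0, 0, 0.5))
  expect_equal(sum(sh), 1)
  # one participant: shares are that participant's distribution
  expect_equal(unname(blockShare(list(short))), c(1, 0, 0, 0))
  # duplicating one participant's blocks does not change their weight
  shortDup <- rbind(short, short)
  expect_equal(blockShare(list(shortDup, long)), sh)
})

test_that("paused percentage is a straight frame fraction with conservation", {
  tl <- data.frame(timestamp_s = (1:1000) / 10,
                   paused = rep(c(TRUE, FALSE), c(170, 830)))
  expect_equal(pausedPercentage(tl), 17)
  expect_equal(pausedPercentage(tl) +
                 100 * mean(!tl$paused), 100)
  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- sample(20:200, 1)
      tl <- data.frame(timestamp_s = (1:n) / 10,
                       paused = sample(c(TRUE, FALSE), n, replace = TRUE))
      lo <- sample(0:(n - 10), 1) / 10
      hi <- lo + sample(5:(n - lo * 10), 1) / 10
      sel <- tl$timestamp_s > lo & tl$timestamp_s <= hi
      expect_equal(pausedPercentage(tl, c(lo, hi)),
                   100 * sum(tl$paused & sel) / sum(sel))
    }
  })
})

test_that("correlations match the textbook formula and validate input", {
  x <- 1:10
  expect_equal(attentionCor(x, 2 * x + 1)$r, 1)
  expect_equal(attentionCor(x, -x)$r, -1)
  withr::with_seed(24, {
    for (rep in 1:20) {
      a <- rnorm(15); b <- rnorm(15)
      got <- attentionCor(a, b)
      want <- oraclePearson(a, b)
      expect_equal(got$r, want$r, tolerance = 1e-12)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  })
  expect_error(attentionCor(rep(1, 5), 1:5), "constant")
  expect_error(attentionCor(1:2, 1:2), "at least 3")
  sp <- attentionCor(1:10, (1:10)^3, method = "spearman")
  expect_equal(sp$r, 1)
})

test_that("reading accuracy exceeds task accuracy when rereading is injected", {
  # end-to-end: generator marks rereading episodes external, the trial
  # evaluation assumes the whole task is internal -- the label-noise
  # pattern that depresses task-phase accuracy
  plan <- makeRereadingPlan(4, 25, 25, rereadS = 10,
                            rereadTrials = 1:4, seed = 31)
  sess <- synthesizeBandPower(plan)
  model <- trainAttentionLda(
    synthesizeBandPower(makeSessionPlan(4, 25, 25, seed = 32)))
  pred <- predict(model, sess)
  accs <- t(vapply(1:4, function(tr) {
    trialAccuracy(makeTrial(frameTimes(sess), pred$state,
                            reading = c((tr - 1) * 50, (tr - 1) * 50 + 25),
                            task = c((tr - 1) * 50 + 25, tr * 50)))
  }, numeric(3)))
  expect_gt(mean(accs[, "reading"]), mean(accs[, "task"]))
  # bin correction recovers part of the loss on flagged trials
  corrected <- vapply(1:4, function(tr) {
    binCorrect(makeTrial(frameTimes(sess), pred$state,
                         reading = c((tr - 1) * 50, (tr - 1) * 50 + 25),
                         task = c((tr - 1) * 50 + 25, tr * 50),
                         rereading = TRUE))$accuracy
  }, numeric(1))
  rawTask <- accs[, "task"]
  expect_gte(mean(corrected), mean(rawTask))
})
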