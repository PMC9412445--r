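test_that("a pure 10 Hz sinusoid concentrates power in alpha, matching the DFT oracle", {
  fs <- 256
  t <- seq_len(fs * 4) / fs
  sig <- matrix(rep(sin(2 * pi * 10 * t), 4), ncol = 4,
                dimnames = list(NULL, museElectrodes()))
  raw <- methods::new("RawEeg", signal = sig, samplingRate = fs,
                      plan = data.frame(), seed = 0L)
  sess <- computeBandPowers(raw)
  bp <- SummarizedExperiment::assay(sess, "logpower")
  tp9 <- bp[1:5, ]   # delta, theta, alpha, beta, gamma at TP9
  expect_true(all(tp9[3, ] > apply(tp9[-3, ], 2, max)))
  # last frame (full window) vs explicit-DFT oracle, all 5 bands
  want <- oracleWindowBandPowers(sig[(fs * 4 - 255):(fs * 4), 1], fs,
                                 bandDefinitions())
  got <- bp[1:5, ncol(bp)]
  expect_equal(unname(got), want, tolerance = 1e-9)
})

test_that("frame schedule: 10 frames per second with zero-padded first second, 90% overlap", {
  fs <- 256
  plan <- makeSessionPlan(1, 5, 5, seed = 1)
  raw <- synthesizeRaw(plan)
  padded <- computeBandPowers(raw)
  expect_equal(ncol(padded), 100)               # 10 s -> 100 frames
  strict <- computeBandPowers(raw, featureConfig(padStart = FALSE))
  expect_equal(ncol(strict), 100 - 9)           # 9 warm-up frames dropped
  expect_equal(frameTimes(strict)[1], 1.0)
  # shared samples between consecutive windows: steps alternate 25/26
  ends <- floor(seq_len(100) * fs / 10)
  steps <- diff(ends)
  expect_true(all(steps %in% c(25L, 26L)))
  expect_true(all((256 - steps) / 256 >= 0.898))
})

test_that("all-zero signal lands on the configured power floor", {
  sig <- matrix(0, nrow = 512, ncol = 4,
                dimnames = list(NULL, museElectrodes()))
  raw <- methods::new("RawEeg", signal = sig, samplingRate = 256,
                      plan = data.frame(), seed = 0L)
  bp <- SummarizedExperiment::assay(computeBandPowers(raw), "logpower")
  expect_true(all(bp == log10(1e-12)))
})

test_that("scaling the signal by c adds 2 log10(c) to every band power", {
  set.seed(31)
  sig <- matrix(rnorm(256 * 8), ncol = 4,
                dimnames = list(NULL, museElectrodes()))
  mk <- function(s) methods::new("RawEeg", signal = s, samplingRate = 256,
                                 plan = data.frame(), seed = 0L)
  b1 <- SummarizedExperiment::assay(computeBandPowers(mk(sig)), "logpower")
  b2 <- SummarizedExperiment::assay(computeBandPowers(mk(10 * sig)), "logpower")
  expect_equal(b2, b1 + 2, tolerance = 1e-12)
})

test_that("summed linear power over non-overlapping bands never exceeds total window power", {
  set.seed(32)
  disjoint <- data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
                         low = c(1, 4.5, 8, 13.5, 30.5),
                         high = c(4, 8, 13, 30, 44))
  sig <- matrix(rnorm(256 * 4), ncol = 4,
                dimnames = list(NULL, museElectrodes()))
  raw <- methods::new("RawEeg", signal = sig, samplingRate = 256,
                      plan = data.frame(), seed = 0L)
  bp <- SummarizedExperiment::assay(
    computeBandPowers(raw, bands = disjoint), "logpower")
  w <- attentionBCI:::hammingTaper(256)
  for (e in 1:4) {
    total <- sum((w * sig[, e])^2) / sum(w^2)   # Parseval: full-spectrum power
    expect_lte(sum(10^bp[(e - 1) * 5 + 1:5, 1]), total + 1e-12)
  }
})

test_that("feature flattening is electrode-major with exact index mapping", {
  set.seed(33)
  vals <- matrix(rnorm(20), nrow = 4, ncol = 5)
  sess <- attentionBCI:::newBandPowerSession(
    matrix(attentionBCI:::flattenGrid(vals), ncol = 1), 1.0, "none")
  fm <- featureMatrix(sess)
  expect_equal(dim(fm), c(1, 20))
  expect_identical(colnames(fm), featureNames())
  for (e in 0:3) for (b in 0:4)
    expect_equal(fm[1, 5 * e + b + 1], vals[e + 1, b + 1])
  # flatten then unflatten round trip
  expect_equal(matrix(fm[1, ], nrow = 4, byrow = TRUE), vals)
})

test_that("degenerate inputs: short signals warn, non-finite samples are named", {
  sig <- matrix(0, nrow = 100, ncol = 4,
                dimnames = list(NULL, museElectrodes()))
  raw <- methods::new("RawEeg", signal = sig, samplingRate = 256,
                      plan = data.frame(), seed = 0L)
  expect_warning(out <- computeBandPowers(raw, featureConfig(padStart = FALSE)),
                 "shorter than one analysis window")
  expect_equal(ncol(out), 0)
  sig[57, 2] <- NA
  rawBad <- methods::new("RawEeg", signal = sig, samplingRate = 256,
                         plan = data.frame(), seed = 0L)
  expect_error(computeBandPowers(rawBad), "index 57.*AF7")
})

test_that("labelFrames applies the majority rule and reports dropped frames", {
  plan <- makeSessionPlan(1, 3, 3, seed = 2)
  raw <- synthesizeRaw(plan)
  sess <- computeBandPowers(raw)
  lab <- labelFrames(sess, plan)
  expect_equal(ncol(lab), 60)
  expect_equal(frameLabels(lab),
               vapply(frameTimes(lab), oracleLabel, character(1), plan = plan))
  # a plan covering only part of the session drops outside frames
  # part plan covers [0, 2]; windows overlapping it by any amount keep a
  # label, so frames up to t = 2.9 stay (their [t-1, t) window touches 2.0)
  part <- makeSessionPlan(1, 1, 1, seed = 2)
  expect_message(lab2 <- labelFrames(sess, part), "dropped 31 frame")
  expect_equal(ncol(lab2), 29)
})

test_that("a labeled 400 s calibration run yields 4000 vectors with the derived class split", {
  plan <- makeSessionPlan(4, 50, 50, seed = 3)
  sess <- synthesizeBandPower(plan)
  fm <- featureMatrix(sess)
  expect_equal(dim(fm), c(4000, 20))
  # class split frozen from the labeling-oracle derivation (tie frames at
  # each phase boundary go to external): 2008 / 1992
  counts <- table(frameLabels(sess))
  expect_equal(as.vector(counts[c("external", "internal")]), c(2008, 1992))
})
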