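test_that("a 400 s plan yields 4000 frames with class counts matching the labeling oracle", {
  plan <- makeSessionPlan(4, 50, 50, seed = 1)
  sess <- synthesizeBandPower(plan)
  expect_equal(ncol(sess), 4000)
  expect_equal(frameTimes(sess), (1:4000) / 10)
  # independent recount of the majority-coverage labels
  want <- vapply(frameTimes(sess), oracleLabel, character(1), plan = plan)
  expect_equal(frameLabels(sess), want)
  # derived from the tie-to-external rule: 505/501/501/501 external runs
  expect_equal(as.vector(table(frameLabels(sess))[c("external", "internal")]),
               c(2008, 1992))
})

test_that("frame count is floor(duration x 10) for ragged plan durations", {
  for (dur in list(c(3.27, 2.9), c(5, 4.04), c(0.55, 0.73))) {
    plan <- makeSessionPlan(1, dur[1], dur[2], seed = 2)
    sess <- synthesizeBandPower(plan)
    expect_equal(ncol(sess), floor(sum(dur) * 10))
  }
})

test_that("generation is deterministic given the seed, across parameters too", {
  plan <- makeSessionPlan(1, 10, 10, seed = 42)
  s1 <- synthesizeBandPower(plan)
  s2 <- synthesizeBandPower(plan)
  expect_identical(SummarizedExperiment::assay(s1),
                   SummarizedExperiment::assay(s2))
  s3 <- synthesizeBandPower(plan, seed = 43)
  expect_false(identical(SummarizedExperiment::assay(s1),
                         SummarizedExperiment::assay(s3)))
  r1 <- synthesizeRaw(plan)
  r2 <- synthesizeRaw(plan)
  expect_identical(r1@signal, r2@signal)
})

test_that("the null generator produces indistinguishable class distributions", {
  plan <- makeSessionPlan(2, 50, 50, seed = 5)
  sess <- synthesizeBandPower(plan, generatorParams(internalShift = 0))
  fm <- featureMatrix(sess)
  lab <- frameLabels(sess)
  p <- stats::t.test(fm[lab == "internal", "tp10_alpha"],
                     fm[lab == "external", "tp10_alpha"])$p.value
  expect_gt(p, 0.01)
})

test_that("internal frames carry the alpha shift at the configured electrodes", {
  plan <- makeSessionPlan(2, 50, 50, seed = 6)
  params <- generatorParams()
  sess <- synthesizeBandPower(plan, params)
  fm <- featureMatrix(sess)
  lab <- frameLabels(sess)
  dMean <- colMeans(fm[lab == "internal", ]) - colMeans(fm[lab == "external", ])
  want <- attentionBCI:::flattenGrid(params$internalShift)
  # 2000 frames/class, sd 0.35 -> SE of the difference ~ 0.011
  expect_true(all(abs(unname(dMean) - want) < 0.05))
  expect_equal(unname(which.max(dMean)),
               which(featureNames() == "tp10_alpha"))
})

test_that("raw synthesis has the right shape and sampling-rate guard", {
  plan <- makeSessionPlan(1, 0.5, 0.5, seed = 7)
  raw <- synthesizeRaw(plan)
  expect_s4_class(raw, "RawEeg")
  expect_equal(dim(raw@signal), c(256, 4))       # 1 s at 256 Hz
  expect_identical(colnames(raw@signal), c("TP9", "AF7", "AF8", "TP10"))
  expect_error(generatorParams(samplingRate = 80), "twice the top band edge")
})

test_that("band-power extraction of the raw signal recovers the target log powers", {
  # single-state long stretch; 0.15 dex tolerance covers band-overlap
  # cross-talk, Hamming leakage and log-of-mean bias
  plan <- makeSessionPlan(1, 199, 1, seed = 8)
  params <- generatorParams()
  raw <- synthesizeRaw(plan, params)
  sess <- labelFrames(computeBandPowers(raw), plan)
  fm <- featureMatrix(sess)
  ext <- colMeans(fm[frameLabels(sess) == "external", ])
  target <- attentionBCI:::flattenGrid(params$baseline)
  expect_true(all(abs(unname(ext) - target) < 0.15))
})

test_that("corruption with zero rates is the identity", {
  plan <- makeSessionPlan(1, 5, 5, seed = 9)
  sess <- synthesizeBandPower(plan)
  out <- corruptFrames(sess, corruptionParams(0, 0, 0))
  expect_equal(SummarizedExperiment::assay(out),
               SummarizedExperiment::assay(sess))
  expect_equal(frameTimes(out), frameTimes(sess))
})

test_that("sample drops follow the configured Bernoulli rate (binomial 3-sigma)", {
  n <- 1e6
  sig <- matrix(0, nrow = n, ncol = 4,
                dimnames = list(NULL, museElectrodes()))
  raw <- methods::new("RawEeg", signal = sig, samplingRate = 256,
                      plan = data.frame(), seed = 1L)
  out <- corruptRaw(raw, corruptionParams(missingRate = 5e-4, jitterSd = 0,
                                          blockDelay = 0), seed = 1)
  dropped <- n - nrow(out)
  expect_true(abs(dropped - n * 5e-4) <= 3 * sqrt(n * 5e-4 * (1 - 5e-4)))
})

test_that("5 ms timestamp jitter keeps ~99.7% of offsets within 15 ms", {
  plan <- makeSessionPlan(1, 500, 500, seed = 10)   # 10^4 frames
  sess <- synthesizeBandPower(plan, generatorParams(noiseSd = 0))
  out <- corruptFrames(sess, corruptionParams(missingRate = 0,
                                              jitterSd = 0.005,
                                              blockDelay = 0.03), seed = 2)
  off <- sort(frameTimes(out)) - (frameTimes(sess) + 0.03)
  cover <- mean(abs(off) <= 0.015)
  expect_gt(cover, 0.993)
  expect_lt(cover, 1)
  # ordering preserved after perturbation by re-sorting
  expect_false(is.unsorted(frameTimes(out)))
})

test_that("corruption parameters are validated", {
  expect_error(corruptionParams(missingRate = 1.5), "\\[0, 1\\]")
  expect_error(corruptionParams(jitterSd = -1), ">= 0")
})
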