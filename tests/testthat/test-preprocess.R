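test_that("block-average down-sampling reproduces hand-computed means", {
  rec <- bilateralRecording(rep(80, 400), rep(80, 400), 100)
  out <- downsample(rec, 25)
  expect_equal(samplingRate(out), 25)
  expect_length(leftVelocity(out), 100)
  expect_true(all(leftVelocity(out) == 80))

  rec2 <- bilateralRecording(1:8, 8:1, 100)
  out2 <- downsample(rec2, 25)
  expect_equal(leftVelocity(out2), c(2.5, 6.5))
  expect_equal(rightVelocity(out2), c(6.5, 2.5))

  long <- bilateralRecording(rnorm(4000, 60), rnorm(4000, 60), 100)
  expect_length(leftVelocity(downsample(long, 25)), 1000)

  expect_error(downsample(rec, 30), "integer multiple")
})

test_that("epoching extracts complete 38 s windows and drops truncated ones", {
  cfg <- preprocessConfig()
  sched <- defaultSchedule()
  n <- (max(sched@onsets) + 30) * 25
  rec <- bilateralRecording(rnorm(n, 60), rnorm(n, 60), 25)
  es <- epochRecording(rec, sched, cfg)
  expect_equal(dim(es), c(950L, 16L))
  expect_equal(relTime(es)[1], -10)

  # first onset too close to the recording start: its pre-window is cut
  schedEarly <- taskSchedule(c(5, 5 + 38 * (1:15)))
  es2 <- epochRecording(rec, schedEarly, cfg)
  expect_equal(ncol(es2), 15L)
  expect_equal(S4Vectors::metadata(es2)$qcLog$droppedOutOfRecording, 1L)
  expect_false(1L %in% trialIndex(es2))

  # recording ending exactly at last onset + 28 s keeps every epoch
  schedFit <- taskSchedule(10 + 38 * (0:3))
  nFit <- (max(schedFit@onsets) + 28) * 25
  recFit <- bilateralRecording(rnorm(nFit, 60), rnorm(nFit, 60), 25)
  expect_equal(ncol(epochRecording(recFit, schedFit, cfg)), 4L)

  expect_error(epochRecording(bilateralRecording(1:50, 1:50, 25),
                              defaultSchedule(), cfg), "zero extractable")
  expect_error(taskSchedule(numeric(0)), "at least one")
})

test_that("heart-cycle integration removes pulsatility, keeps slow trends", {
  cfg <- preprocessConfig()
  # constant signal: no troughs, passes through with a warning flag
  esConst <- makeEpochSet(function(rel, j) rep(100, length(rel)),
                          function(rel, j) rep(100, length(rel)), nTrials = 1)
  expect_warning(out <- heartCycleIntegrate(esConst), "fewer than 2")
  expect_equal(DopplerLI:::assayL(out), DopplerLI:::assayL(esConst))
  expect_true(all(SummarizedExperiment::colData(out)$hciWarn))

  # pure sinusoid around 100: per-cycle means are the offset
  f <- 1.2
  esSin <- makeEpochSet(function(rel, j) 100 + 20 * sin(2 * pi * f * rel),
                        function(rel, j) 100 + 20 * sin(2 * pi * f * rel),
                        nTrials = 2)
  outSin <- heartCycleIntegrate(esSin)
  expect_lt(max(abs(DopplerLI:::assayL(outSin) - 100)), 0.5)
  expect_false(any(SummarizedExperiment::colData(outSin)$hciWarn))

  # sinusoid on a linear trend: cycle means track the trend at midpoints
  esTrend <- makeEpochSet(
    function(rel, j) 100 + rel + 20 * sin(2 * pi * f * rel),
    function(rel, j) 100 + rel + 20 * sin(2 * pi * f * rel), nTrials = 1)
  outTrend <- heartCycleIntegrate(esTrend)
  rel <- relTime(outTrend)
  interior <- rel > -9 & rel < 27
  expect_lt(max(abs(DopplerLI:::assayL(outTrend)[interior, 1] -
                      (100 + rel[interior]))), 0.5)
})

test_that("artifact rule: one outlier replaced, multiple exclude the epoch", {
  cfg <- preprocessConfig()
  # discrete repeated values: the extreme quantiles coincide with the
  # extremes themselves, so nothing is strictly outside the bounds
  esClean <- makeEpochSet(function(rel, j) rep(c(90, 100, 110), length.out = length(rel)),
                          function(rel, j) rep(c(95, 100, 105), length.out = length(rel)),
                          nTrials = 4)
  outClean <- detectArtifacts(esClean, cfg)
  expect_equal(DopplerLI:::assayL(outClean), DopplerLI:::assayL(esClean))
  expect_true(all(qcStatus(outClean) == "kept"))

  # a single 10x spike is replaced by the epoch mean excluding the spike
  esSpike <- makeEpochSet(function(rel, j) rep(100, length(rel)),
                          function(rel, j) rep(100, length(rel)), nTrials = 4)
  L <- DopplerLI:::assayL(esSpike)
  L[200, 2] <- 1000
  SummarizedExperiment::assay(esSpike, "left") <- L
  outSpike <- detectArtifacts(esSpike, cfg)
  expect_true(all(qcStatus(outSpike) == "kept"))
  expect_equal(unname(DopplerLI:::assayL(outSpike)[200, 2]), 100)  # manual recomputation
  expect_equal(S4Vectors::metadata(outSpike)$qcLog$outliersReplaced, 1L)

  # a dropout plus a spike within one epoch exclude it; the others stay
  esTwo <- makeEpochSet(function(rel, j) rep(100, length(rel)),
                        function(rel, j) rep(100, length(rel)), nTrials = 4)
  L <- DopplerLI:::assayL(esTwo)
  L[c(100, 300), 3] <- c(5, 1000)
  SummarizedExperiment::assay(esTwo, "left") <- L
  outTwo <- detectArtifacts(esTwo, cfg)
  expect_equal(qcStatus(outTwo),
               c("kept", "kept", "excluded_artifact", "kept"))
})

test_that("normalization rescales each channel to mean 100 exactly", {
  es <- makeEpochSet(function(rel, j) rep(c(1, 3), length.out = length(rel)),
                     function(rel, j) rep(4, length(rel)), nTrials = 2)
  out <- normalizeEpochs(es)
  expect_true(isNormalized(out))
  expect_equal(sort(unique(as.vector(DopplerLI:::assayL(out)))), c(50, 150))
  expect_equal(mean(DopplerLI:::assayL(out)), 100, tolerance = 1e-12)
  expect_equal(mean(DopplerLI:::assayR(out)), 100, tolerance = 1e-12)

  # idempotence: renormalizing normalized data changes nothing
  expect_equal(DopplerLI:::assayL(normalizeEpochs(out)),
               DopplerLI:::assayL(out))

  esNeg <- makeEpochSet(function(rel, j) rep(-1, length(rel)),
                        function(rel, j) rep(1, length(rel)), nTrials = 2)
  expect_error(normalizeEpochs(esNeg), "positive")
})

test_that("baseline correction subtracts the pre-instruction rest mean", {
  cfg <- preprocessConfig()
  # flat epoch equal to its baseline: all zeros afterwards
  esFlat <- makeEpochSet(function(rel, j) rep(98, length(rel)),
                         function(rel, j) rep(98, length(rel)),
                         nTrials = 2, normalized = TRUE)
  outFlat <- baselineCorrect(esFlat, cfg)
  expect_true(all(DopplerLI:::assayL(outFlat) == 0))

  # baseline 98, task plateau 103: corrected POI is +5
  es <- makeEpochSet(function(rel, j) ifelse(rel < 0, 98, 103),
                     function(rel, j) ifelse(rel < 0, 98, 103),
                     nTrials = 2, normalized = TRUE)
  out <- baselineCorrect(es, cfg)
  poi <- DopplerLI:::windowIdx(relTime(out), cfg@poiWindow)
  expect_equal(unique(as.vector(DopplerLI:::assayL(out)[poi, ])), 5)
  # corrected baseline mean is zero per epoch and channel
  bidx <- DopplerLI:::windowIdx(relTime(out), cfg@baselineWindow)
  expect_equal(max(abs(colMeans(DopplerLI:::assayL(out)[bidx, ]))), 0,
               tolerance = 1e-9)
  # pre-subtraction values are retained for the range filter
  expect_true("leftNorm" %in% SummarizedExperiment::assayNames(out))
  # idempotence
  expect_equal(DopplerLI:::assayL(baselineCorrect(out, cfg)),
               DopplerLI:::assayL(out))

  expect_error(baselineCorrect(makeEpochSet(function(rel, j) rel,
                                            function(rel, j) rel),
                               cfg), "normalized")
})

test_that("range rejection uses strict 60/140 bounds on normalized values", {
  cfg <- preprocessConfig()
  mk <- function(vals) {
    makeEpochSet(function(rel, j) rep(vals[j], length(rel)),
                 function(rel, j) rep(100, length(rel)),
                 nTrials = length(vals), normalized = TRUE)
  }
  # boundary enumeration: 60.0 and 140.0 are kept, 59.9 and 140.1 are not
  out <- rejectOutOfRange(mk(c(60, 140, 59.9, 140.1, 100)), cfg)
  expect_equal(qcStatus(out),
               c("kept", "kept", "excluded_range", "excluded_range", "kept"))

  expect_true(all(qcStatus(rejectOutOfRange(mk(c(100, 120)), cfg)) == "kept"))
  expect_error(rejectOutOfRange(mk(c(59, 141)), cfg), "insufficient epochs")
})

test_that("manual exclusions are honoured and never automated", {
  es <- makeEpochSet(function(rel, j) rep(100, length(rel)),
                     function(rel, j) rep(100, length(rel)), nTrials = 4)
  out <- excludeManually(es, c(2, 4))
  expect_equal(qcStatus(out),
               c("kept", "excluded_manual", "kept", "excluded_manual"))
})

test_that("the full chain is channel-symmetric and QC counts never grow", {
  cfg <- preprocessConfig()
  sim <- simulateSession(quickSim(nTrials = 6, traitLI = -2, seed = 11))
  es1 <- preprocessSession(sim$recording, sim$schedule, cfg)
  es2 <- preprocessSession(swapChannels(sim$recording), sim$schedule, cfg)
  expect_equal(DopplerLI:::assayL(es2), DopplerLI:::assayR(es1))
  expect_equal(DopplerLI:::assayR(es2), DopplerLI:::assayL(es1))
  expect_equal(qcStatus(es2), qcStatus(es1))

  # kept-epoch count is monotonically non-increasing through QC stages
  simArt <- simulateSession(quickSim(nTrials = 6, seed = 3, spikeRate = 2,
                                     dropoutRate = 2))
  es <- epochRecording(downsample(simArt$recording, 25), simArt$schedule, cfg)
  n0 <- sum(qcStatus(es) == "kept")
  es <- detectArtifacts(es, cfg)
  n1 <- sum(qcStatus(es) == "kept")
  es <- normalizeEpochs(es)
  es <- suppressWarnings(heartCycleIntegrate(es))
  es <- baselineCorrect(es, cfg)
  es <- rejectOutOfRange(es, cfg)
  n2 <- sum(qcStatus(es) == "kept")
  expect_true(n0 >= n1 && n1 >= n2)
})

test_that("heart-cycle integration leaves POI means nearly unchanged on
           artifact-free input", {
  cfg <- preprocessConfig()
  sim <- simulateSession(quickSim(nTrials = 6, traitLI = -2, seed = 5))
  base <- normalizeEpochs(detectArtifacts(
    epochRecording(downsample(sim$recording, 25), sim$schedule, cfg), cfg))
  withHCI <- baselineCorrect(
    suppressWarnings(heartCycleIntegrate(base)), cfg)
  without <- baselineCorrect(base, cfg)
  poiWith <- perEpochLI(withHCI, cfg)
  poiWithout <- perEpochLI(without, cfg)
  expect_lt(max(abs(poiWith - poiWithout)), 1)
})
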