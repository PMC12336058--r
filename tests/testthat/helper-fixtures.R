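# Epoch-set fixtures built in code.

# An EpochSet on the default grid whose left/right assays are filled from
# functions of relative time (vectorized), one column per trial.
makeEpochSet <- function(leftFun, rightFun, nTrials = 4,
                         cfg = preprocessConfig(), normalized = FALSE,
                         baselineCorrected = FALSE) {
  rate <- cfg@targetRate
  nWin <- round((cfg@epochWindow[2] - cfg@epochWindow[1]) * rate)
  rel <- cfg@epochWindow[1] + (seq_len(nWin) - 1) / rate
  left <- vapply(seq_len(nTrials), function(j) leftFun(rel, j), rel)
  right <- vapply(seq_len(nTrials), function(j) rightFun(rel, j), rel)
  es <- DopplerLI:::newEpochSet(left, right, rel, seq_len(nTrials),
                                rep("A", nTrials), rate)
  es <- DopplerLI:::metaSet(es, "normalized", normalized)
  DopplerLI:::metaSet(es, "baselineCorrected", baselineCorrected)
}

# Baseline-corrected epochs whose per-epoch POI (right - left) means are
# exactly `diffs` (constant over the POI, zero elsewhere).
makeDiffEpochs <- function(diffs, cfg = preprocessConfig()) {
  makeEpochSet(function(rel, j) rep(0, length(rel)),
               function(rel, j)
                 ifelse(rel >= cfg@poiWindow[1] & rel < cfg@poiWindow[2],
                        diffs[j], 0),
               nTrials = length(diffs), cfg = cfg,
               normalized = TRUE, baselineCorrected = TRUE)
}

swapChannels <- function(rec)
  bilateralRecording(rightVelocity(rec), leftVelocity(rec),
                     samplingRate(rec))

# Short session config for tests where 16 trials are not needed.
quickSim <- function(nTrials = 6, ...)
  sessionSimConfig(schedule = defaultSchedule(nTrials), ...)
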