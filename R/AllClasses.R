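#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats approx filter qnorm qt quantile rnorm rpois runif rbinom
#'   sd var pf pnorm pt aggregate complete.cases cor.test t.test median
#' @importFrom utils read.csv write.csv packageVersion combn head tail
NULL

#' Bilateral cerebral blood flow velocity recording
#'
#' Container for a synchronized two-channel (left/right middle cerebral
#' artery) velocity recording sampled at a common rate.
#'
#' @slot samplingRate sampling rate in Hz.
#' @slot left,right numeric velocity series in cm/s, equal length.
#'
#' @seealso [bilateralRecording()], [downsample()], [epochRecording()]
#' @exportClass BilateralRecording
setClass("BilateralRecording",
  representation(samplingRate = "numeric", left = "numeric", right = "numeric"))

setValidity("BilateralRecording", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@left) != length(object@right))
    msg <- c(msg, "left and right channels must have equal length")
  if (length(msg)) msg else TRUE
})

#' Construct a BilateralRecording
#'
#' @param left,right numeric velocity series (cm/s) for the left and right
#'   channels; must have equal length.
#' @param samplingRate sampling rate in Hz.
#' @return A [BilateralRecording-class] object.
#' @examples
#' rec <- bilateralRecording(rep(55, 400), rep(54, 400), samplingRate = 100)
#' duration(rec)
#' @export
bilateralRecording <- function(left, right, samplingRate) {
  new("BilateralRecording", samplingRate = as.numeric(samplingRate),
      left = as.numeric(left), right = as.numeric(right))
}

#' Task schedule for a word-generation session
#'
#' Trial timing of the covert word-generation paradigm: each trial is an
#' instruction screen followed by a generation phase and a rest period.
#' Onsets refer to the instruction-screen onset in seconds from the start
#' of the recording.
#'
#' @slot onsets instruction-screen onsets (s), strictly increasing.
#' @slot instructionDur,taskDur,restDur durations (s) of the instruction
#'   screen, the word-generation phase and the rest period.
#' @slot letters one cue letter per trial.
#' @exportClass TaskSchedule
setClass("TaskSchedule",
  representation(onsets = "numeric", instructionDur = "numeric",
                 taskDur = "numeric", restDur = "numeric",
                 letters = "character"))

setValidity("TaskSchedule", function(object) {
  msg <- character(0)
  if (length(object@onsets) == 0L)
    msg <- c(msg, "schedule must contain at least one trial onset")
  if (is.unsorted(object@onsets, strictly = TRUE))
    msg <- c(msg, "trial onsets must be strictly increasing")
  if (length(object@onsets) != length(object@letters))
    msg <- c(msg, "number of onsets must equal number of letters")
  gap <- object@instructionDur + object@taskDur
  if (length(object@onsets) > 1L && any(diff(object@onsets) < gap - 1e-9))
    msg <- c(msg, "inter-onset gaps must cover instruction plus task duration")
  if (length(msg)) msg else TRUE
})

#' @rdname TaskSchedule-class
#' @param onsets instruction onsets in seconds.
#' @param instructionDur,taskDur,restDur trial-phase durations in seconds.
#' @param letters cue letters, one per onset.
#' @export
taskSchedule <- function(onsets, instructionDur = 3, taskDur = 20,
                         restDur = 15, letters = NULL) {
  if (is.null(letters)) letters <- defaultLetters(length(onsets))
  new("TaskSchedule", onsets = as.numeric(onsets),
      instructionDur = instructionDur, taskDur = taskDur, restDur = restDur,
      letters = as.character(letters))
}

defaultLetters <- function(n) {
  base <- c("S", "B", "K", "V", "P", "A", "O", "T",
            "G", "R", "M", "D", "H", "L", "W", "Z")
  rep_len(base, n)
}

#' Default 16-trial word-generation schedule
#'
#' Sixteen trials (one cue letter each) of 3 s instruction + 20 s generation
#' + 15 s rest, preceded by a lead-in rest so that the first pre-stimulus
#' window lies inside the recording.
#'
#' @param nTrials number of trials.
#' @param leadIn rest before the first instruction onset (s).
#' @return A [TaskSchedule-class].
#' @export
defaultSchedule <- function(nTrials = 16, leadIn = 15) {
  taskSchedule(onsets = leadIn + 38 * (seq_len(nTrials) - 1),
               letters = defaultLetters(nTrials))
}

#' Preprocessing configuration
#'
#' Parameters of the epoching and quality-control chain. All windows are in
#' seconds relative to the instruction-screen onset and are half-open
#' `[from, to)` on the sample grid.
#'
#' @slot targetRate analysis sampling rate (Hz).
#' @slot epochWindow epoch extent, default `c(-10, 28)` (38 s).
#' @slot quantileBounds per-channel session quantiles delimiting
#'   spike/dropout samples, default `c(1e-4, 0.9999)`.
#' @slot rangeBounds normalized-velocity bounds (% of channel mean) outside
#'   which an epoch is rejected, default `c(60, 140)` (strict inequalities).
#' @slot baselineWindow pre-instruction rest used as baseline, default
#'   `c(-8, 0)`.
#' @slot poiWindow period of interest over which the laterality index is
#'   averaged, default `c(6, 23)` (17 s starting 3 s into word generation).
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(targetRate = "numeric", epochWindow = "numeric",
                 quantileBounds = "numeric", rangeBounds = "numeric",
                 baselineWindow = "numeric", poiWindow = "numeric"))

setValidity("PreprocessConfig", function(object) {
  msg <- character(0)
  w <- object@epochWindow
  if (length(w) != 2L || !(w[1] < 0 && 0 < w[2]))
    msg <- c(msg, "epochWindow must straddle the instruction onset (pre < 0 < post)")
  inWin <- function(x) x[1] >= w[1] - 1e-9 && x[2] <= w[2] + 1e-9 && x[1] < x[2]
  if (!inWin(object@baselineWindow))
    msg <- c(msg, "baselineWindow must lie inside epochWindow")
  if (!inWin(object@poiWindow))
    msg <- c(msg, "poiWindow must lie inside epochWindow")
  if (object@targetRate <= 0)
    msg <- c(msg, "targetRate must be positive")
  qb <- object@quantileBounds
  if (!(qb[1] >= 0 && qb[2] <= 1 && qb[1] < qb[2]))
    msg <- c(msg, "quantileBounds must be increasing probabilities")
  if (object@rangeBounds[1] >= object@rangeBounds[2])
    msg <- c(msg, "rangeBounds must be increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname PreprocessConfig-class
#' @param targetRate,epochWindow,quantileBounds,rangeBounds,baselineWindow,poiWindow
#'   see the class slots.
#' @export
preprocessConfig <- function(targetRate = 25, epochWindow = c(-10, 28),
                             quantileBounds = c(1e-4, 0.9999),
                             rangeBounds = c(60, 140),
                             baselineWindow = c(-8, 0),
                             poiWindow = c(6, 23)) {
  new("PreprocessConfig", targetRate = targetRate, epochWindow = epochWindow,
      quantileBounds = quantileBounds, rangeBounds = rangeBounds,
      baselineWindow = baselineWindow, poiWindow = poiWindow)
}

QC_LEVELS <- c("kept", "excluded_artifact", "excluded_range", "excluded_manual")

#' Epoched two-channel velocity data
#'
#' An `EpochSet` holds per-trial windows of the left and right velocity
#' channels on a common relative time grid. It extends
#' \linkS4class{SummarizedExperiment}: rows are time points (with
#' `rowData()$relTime` in seconds relative to instruction onset), columns are
#' epochs (with `colData()` carrying `trialIndex`, `letter` and `qcStatus`),
#' and assays `"left"` and `"right"` hold the velocity windows. After
#' baseline correction, assays `"leftNorm"`/`"rightNorm"` retain the
#' normalized pre-subtraction values used by the range filter.
#'
#' @seealso [epochRecording()], [keptEpochs()], [qcStatus()]
#' @exportClass EpochSet
setClass("EpochSet", contains = "SummarizedExperiment")

setValidity("EpochSet", function(object) {
  msg <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("left", "right") %in% an))
    msg <- c(msg, "assays 'left' and 'right' are required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("trialIndex", "qcStatus") %in% colnames(cd)))
    msg <- c(msg, "colData must contain trialIndex and qcStatus")
  else if (!all(cd$qcStatus %in% QC_LEVELS))
    msg <- c(msg, "qcStatus contains unknown levels")
  rd <- SummarizedExperiment::rowData(object)
  if (!("relTime" %in% colnames(rd)))
    msg <- c(msg, "rowData must contain relTime")
  if (length(msg)) msg else TRUE
})

newEpochSet <- function(left, right, relTime, trialIndex, letter,
                        samplingRate, qcLog = list()) {
  stopifnot(identical(dim(left), dim(right)), nrow(left) == length(relTime))
  cn <- paste0("epoch", trialIndex)
  dimnames(left) <- dimnames(right) <- list(NULL, cn)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(left = left, right = right),
    rowData = S4Vectors::DataFrame(relTime = relTime),
    colData = S4Vectors::DataFrame(
      trialIndex = as.integer(trialIndex),
      letter = as.character(letter),
      qcStatus = rep("kept", length(trialIndex)),
      hciWarn = rep(FALSE, length(trialIndex)),
      row.names = cn))
  S4Vectors::metadata(se) <- list(samplingRate = samplingRate,
                                  normalized = FALSE,
                                  baselineCorrected = FALSE,
                                  heartIntegrated = FALSE,
                                  qcLog = qcLog)
  new("EpochSet", se)
}

#' Per-session laterality result
#'
#' Laterality index (LI) with epoch-wise uncertainty and dominance
#' classification. The LI is the mean over kept epochs of the
#' period-of-interest average of (right - left) baseline-corrected
#' normalized velocity; negative values indicate leftward (left-hemisphere)
#' dominance.
#'
#' @slot li laterality index (Delta-% units).
#' @slot se epoch-to-epoch standard error of the LI.
#' @slot ciLow,ciHigh confidence bounds at `level`.
#' @slot nEpochs number of kept epochs.
#' @slot perEpochLI per-epoch LIs.
#' @slot liOdd,liEven split-half LIs over odd/even design trials (NA when a
#'   half is empty).
#' @slot label trichotomous dominance label: `"LLD"`, `"BLD"` or `"RLD"`.
#' @slot dichotomous `"left"` or `"right"` by the sign of the LI.
#' @slot ciMethod `"t"` or `"normal"`; `level` the confidence level.
#' @exportClass LateralityResult
setClass("LateralityResult",
  representation(li = "numeric", se = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", nEpochs = "integer",
                 perEpochLI = "numeric", liOdd = "numeric", liEven = "numeric",
                 label = "character", dichotomous = "character",
                 ciMethod = "character", level = "numeric"))

setValidity("LateralityResult", function(object) {
  msg <- character(0)
  if (object@nEpochs != length(object@perEpochLI))
    msg <- c(msg, "nEpochs must equal length(perEpochLI)")
  if (object@se < 0) msg <- c(msg, "se must be non-negative")
  if (!(object@ciLow <= object@li + 1e-12 && object@li <= object@ciHigh + 1e-12))
    msg <- c(msg, "confidence interval must contain the LI")
  if (length(msg)) msg else TRUE
})

#' Session-simulation configuration
#'
#' Generative model of a bilateral velocity session: each channel is
#' baseline * (1 + pulsatility) * (1 + (evoked response + noise)/100), with
#' the task-evoked rise split antisymmetrically across hemispheres so that
#' the laterality recovered by the pipeline equals `traitLI + stateOffset`
#' (the trait/state decomposition; measurement noise adds on top).
#'
#' @slot schedule a [TaskSchedule-class].
#' @slot samplingRate native recording rate (Hz).
#' @slot traitLI stable person-specific laterality (Delta-%, negative =
#'   leftward).
#' @slot stateOffset session-specific laterality shift (Delta-%).
#' @slot hrBpm cardiac rate (beats per minute).
#' @slot pulsatilityFrac cardiac waveform amplitude as fraction of the mean.
#' @slot responseAmplitude shared task-evoked velocity rise (%).
#' @slot responseOnsetLag hemodynamic lag: the response ramps from task
#'   onset and reaches plateau this many seconds later (s).
#' @slot noiseSd stationary sd of the AR(1) measurement noise (%).
#' @slot noiseAR AR(1) coefficient at the native rate.
#' @slot spikeRate,dropoutRate artifact rates (events per minute).
#' @slot spikeTimes,dropoutTimes explicit artifact times (s), added on top
#'   of the random ones.
#' @slot baselineLeft,baselineRight mean velocities (cm/s).
#' @slot seed integer RNG seed.
#' @exportClass SessionSimConfig
setClass("SessionSimConfig",
  representation(schedule = "TaskSchedule", samplingRate = "numeric",
                 traitLI = "numeric", stateOffset = "numeric",
                 hrBpm = "numeric", pulsatilityFrac = "numeric",
                 responseAmplitude = "numeric", responseOnsetLag = "numeric",
                 noiseSd = "numeric", noiseAR = "numeric",
                 spikeRate = "numeric", dropoutRate = "numeric",
                 spikeTimes = "numeric", dropoutTimes = "numeric",
                 baselineLeft = "numeric", baselineRight = "numeric",
                 seed = "numeric"))

setValidity("SessionSimConfig", function(object) {
  msg <- character(0)
  if (object@pulsatilityFrac < 0 || object@pulsatilityFrac >= 1)
    msg <- c(msg, "pulsatilityFrac must be in [0, 1)")
  if (object@spikeRate < 0 || object@dropoutRate < 0)
    msg <- c(msg, "artifact rates must be non-negative")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (abs(object@noiseAR) >= 1) msg <- c(msg, "noiseAR must lie in (-1, 1)")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SessionSimConfig-class
#' @param schedule,samplingRate,traitLI,stateOffset,hrBpm,pulsatilityFrac,responseAmplitude,responseOnsetLag,noiseSd,noiseAR,spikeRate,dropoutRate,spikeTimes,dropoutTimes,baselineLeft,baselineRight,seed
#'   see the class slots.
#' @export
sessionSimConfig <- function(schedule = defaultSchedule(), samplingRate = 100,
                             traitLI = 0, stateOffset = 0, hrBpm = 70,
                             pulsatilityFrac = 0.25, responseAmplitude = 4,
                             responseOnsetLag = 3, noiseSd = 1, noiseAR = 0.9,
                             spikeRate = 0, dropoutRate = 0,
                             spikeTimes = numeric(0),
                             dropoutTimes = numeric(0),
                             baselineLeft = 55, baselineRight = 54,
                             seed = 1) {
  new("SessionSimConfig", schedule = schedule, samplingRate = samplingRate,
      traitLI = traitLI, stateOffset = stateOffset, hrBpm = hrBpm,
      pulsatilityFrac = pulsatilityFrac, responseAmplitude = responseAmplitude,
      responseOnsetLag = responseOnsetLag, noiseSd = noiseSd, noiseAR = noiseAR,
      spikeRate = spikeRate, dropoutRate = dropoutRate,
      spikeTimes = spikeTimes, dropoutTimes = dropoutTimes,
      baselineLeft = baselineLeft, baselineRight = baselineRight,
      seed = seed)
}
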