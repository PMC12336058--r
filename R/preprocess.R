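#' Down-sample a bilateral recording by block averaging
#'
#' Each channel is averaged over consecutive non-overlapping blocks of
#' `samplingRate(rec) / targetRate` samples (the ratio must be an integer),
#' which also acts as an anti-aliasing filter. Trailing samples that do not
#' fill a block are dropped.
#'
#' @param rec a [BilateralRecording-class].
#' @param targetRate output rate in Hz.
#' @return A [BilateralRecording-class] at `targetRate`.
#' @examples
#' rec <- bilateralRecording(1:8, 8:1, samplingRate = 100)
#' leftVelocity(downsample(rec, 25))  # block means of 4: 2.5, 6.5
#' @export
downsample <- function(rec, targetRate = 25) {
  stopifnot(is(rec, "BilateralRecording"))
  ratio <- rec@samplingRate / targetRate
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("sampling rate (", rec@samplingRate,
         " Hz) is not an integer multiple of the target rate (",
         targetRate, " Hz)")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  block <- function(v) {
    m <- (length(v) %/% ratio) * ratio
    colMeans(matrix(v[seq_len(m)], nrow = ratio))
  }
  bilateralRecording(block(rec@left), block(rec@right), targetRate)
}

#' Segment a recording into per-trial epochs
#'
#' Extracts one window per trial, spanning `cfg@epochWindow` (default
#' -10 to +28 s, i.e. 38 s) around the instruction onset. Trials whose
#' window extends beyond the recording are dropped and counted in the QC
#' log (`metadata(x)$qcLog$droppedOutOfRecording`).
#'
#' @param rec a [BilateralRecording-class] already at `cfg@targetRate`.
#' @param sched a [TaskSchedule-class].
#' @param cfg a [PreprocessConfig-class].
#' @return An [EpochSet-class].
#' @export
epochRecording <- function(rec, sched, cfg = preprocessConfig()) {
  stopifnot(is(rec, "BilateralRecording"), is(sched, "TaskSchedule"))
  if (abs(rec@samplingRate - cfg@targetRate) > 1e-8)
    stop("recording must be at the target rate (", cfg@targetRate,
         " Hz); call downsample() first")
  if (length(sched@onsets) == 0L) stop("empty task schedule")
  rate <- cfg@targetRate
  nWin <- as.integer(round((cfg@epochWindow[2] - cfg@epochWindow[1]) * rate))
  relTime <- cfg@epochWindow[1] + (seq_len(nWin) - 1L) / rate
  n <- length(rec@left)
  start <- as.integer(round((sched@onsets + cfg@epochWindow[1]) * rate)) + 1L
  ok <- start >= 1L & (start + nWin - 1L) <= n
  if (!any(ok)) stop("zero extractable epochs: recording too short")
  idx <- outer(seq_len(nWin) - 1L, start[ok], `+`)
  left <- matrix(rec@left[idx], nrow = nWin)
  right <- matrix(rec@right[idx], nrow = nWin)
  es <- newEpochSet(left, right, relTime,
                    trialIndex = which(ok), letter = sched@letters[ok],
                    samplingRate = rate)
  qcLogAppend(es, "droppedOutOfRecording", sum(!ok))
}

#' Mark epochs for manual exclusion
#'
#' Visual-inspection rejections are supplied externally as trial indices;
#' they are never automated.
#'
#' @param epochs an [EpochSet-class].
#' @param trials design trial indices to exclude.
#' @return The [EpochSet-class] with `qcStatus = "excluded_manual"` set.
#' @export
excludeManually <- function(epochs, trials) {
  cd <- SummarizedExperiment::colData(epochs)
  hit <- cd$trialIndex %in% trials & cd$qcStatus == "kept"
  SummarizedExperiment::colData(epochs)$qcStatus[hit] <- "excluded_manual"
  qcLogAppend(epochs, "manualExclusions", sum(hit))
}

#' Detect and handle spikes and dropouts
#'
#' Per channel, session-level quantile bounds (`cfg@quantileBounds`, default
#' 0.0001-0.9999) are computed over all epoched samples. Within an epoch,
#' counting outlier samples across both channels: zero outliers leave the
#' epoch unchanged; exactly one is replaced by the mean of its
#' epoch-channel (computed excluding the outlier); two or more exclude the
#' epoch (`qcStatus = "excluded_artifact"`).
#'
#' @inheritParams epochRecording
#' @param epochs an [EpochSet-class], not yet normalized.
#' @return The filtered [EpochSet-class].
#' @export
detectArtifacts <- function(epochs, cfg = preprocessConfig()) {
  stopifnot(is(epochs, "EpochSet"))
  if (isNormalized(epochs))
    stop("artifact detection must run before normalization")
  L <- assayL(epochs); R <- assayR(epochs)
  bl <- quantile(L, cfg@quantileBounds, names = FALSE, type = 7)
  br <- quantile(R, cfg@quantileBounds, names = FALSE, type = 7)
  outL <- L < bl[1] | L > bl[2]
  outR <- R < br[1] | R > br[2]
  perEpoch <- colSums(outL) + colSums(outR)
  cd <- SummarizedExperiment::colData(epochs)
  nRepl <- 0L
  for (j in which(perEpoch == 1L & cd$qcStatus == "kept")) {
    if (any(outL[, j])) {
      i <- which(outL[, j])
      L[i, j] <- mean(L[-i, j])
    } else {
      i <- which(outR[, j])
      R[i, j] <- mean(R[-i, j])
    }
    nRepl <- nRepl + 1L
  }
  excl <- perEpoch >= 2L & cd$qcStatus == "kept"
  SummarizedExperiment::colData(epochs)$qcStatus[excl] <- "excluded_artifact"
  epochs <- setAssays(epochs, L, R)
  epochs <- qcLogAppend(epochs, "outliersReplaced", nRepl)
  qcLogAppend(epochs, "epochsExcludedArtifact", sum(excl))
}

#' Normalize velocities to percent of the channel mean
#'
#' Each channel is divided by its session-level mean over kept epochs and
#' multiplied by 100, so velocities become percent of the typical session
#' velocity (independent of insonation angle and vessel diameter). After
#' normalization each channel's mean over kept epochs is exactly 100.
#'
#' @param epochs an [EpochSet-class] with artifact handling already applied.
#' @return The normalized [EpochSet-class].
#' @export
normalizeEpochs <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  kept <- qcStatus(epochs) == "kept"
  if (!any(kept)) stop("insufficient epochs: no kept epochs to normalize")
  mL <- mean(assayL(epochs)[, kept])
  mR <- mean(assayR(epochs)[, kept])
  if (mL <= 0 || mR <= 0)
    stop("non-physiological input: channel mean velocity must be positive")
  epochs <- setAssays(epochs, assayL(epochs) / mL * 100,
                      assayR(epochs) / mR * 100)
  metaSet(epochs, "normalized", TRUE)
}

# Diastolic troughs: strict local minima separated by >= minSep samples;
# where two candidates are closer, the lower one wins.
findTroughs <- function(v, minSep) {
  d <- diff(v)
  cand <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  if (length(cand) < 2L) return(cand)
  keep <- cand[1]
  for (k in cand[-1]) {
    last <- keep[length(keep)]
    if (k - last >= minSep) keep <- c(keep, k)
    else if (v[k] < v[last]) keep[length(keep)] <- k
  }
  keep
}

# Parabolic sub-sample refinement of trough positions.
refineTroughs <- function(v, tr) {
  inner <- tr > 1L & tr < length(v)
  d <- rep(0, length(tr))
  i <- tr[inner]
  den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  ok <- den > 1e-12
  d[inner][ok] <- pmin(0.5, pmax(-0.5,
    0.5 * (v[i - 1L] - v[i + 1L])[ok] / den[ok]))
  tr + d
}

integrateChannel <- function(v, minSep) {
  tr <- findTroughs(v, minSep)
  if (length(tr) < 2L) return(list(v = v, warn = TRUE))
  p <- refineTroughs(v, tr)
  # cumulative trapezoid of the linear interpolant; fractional end-points
  ct <- c(0, cumsum((v[-1] + v[-length(v)]) / 2))
  intTo <- function(x) {
    i <- pmin(floor(x), length(v) - 1L)
    th <- x - i
    ct[i] + th * v[i] + th^2 / 2 * (v[i + 1L] - v[i])
  }
  from <- p[-length(p)]
  to <- p[-1]
  means <- (intTo(to) - intTo(from)) / (to - from)
  mid <- (from + to) / 2
  list(v = approx(mid, means, xout = seq_along(v), rule = 2)$y, warn = FALSE)
}

#' Remove cardiac pulsatility by heart-cycle integration
#'
#' Per channel and epoch, cardiac cycles are delimited by successive
#' diastolic troughs (local minima at least `minIBI` seconds apart, default
#' 0.33 s, i.e. up to 180 bpm); each cycle is replaced by its time-mean at
#' the cycle midpoint and values are linearly re-interpolated onto the
#' original grid (constant extension at the window edges). Windows with
#' fewer than two troughs (e.g. constant signals) pass through unchanged
#' and are flagged in `colData()$hciWarn`.
#'
#' @param epochs an [EpochSet-class], not yet baseline-corrected.
#' @param minIBI minimum inter-beat interval in seconds.
#' @return The [EpochSet-class] with pulsatility removed.
#' @export
heartCycleIntegrate <- function(epochs, minIBI = 0.33) {
  stopifnot(is(epochs, "EpochSet"))
  if (isBaselineCorrected(epochs))
    stop("heart-cycle integration must run before baseline correction")
  minSep <- max(2L, as.integer(ceiling(minIBI * samplingRate(epochs))))
  L <- assayL(epochs); R <- assayR(epochs)
  warn <- logical(ncol(L))
  for (j in seq_len(ncol(L))) {
    a <- integrateChannel(L[, j], minSep)
    b <- integrateChannel(R[, j], minSep)
    L[, j] <- a$v; R[, j] <- b$v
    warn[j] <- a$warn || b$warn
  }
  if (any(warn))
    warning(sum(warn), " epoch(s) had fewer than 2 detected troughs; ",
            "passed through unchanged")
  SummarizedExperiment::colData(epochs)$hciWarn <- warn
  epochs <- setAssays(epochs, L, R)
  metaSet(epochs, "heartIntegrated", TRUE)
}

#' Baseline-correct epochs against pre-instruction rest
#'
#' Per epoch and channel, the mean over `cfg@baselineWindow` (default the
#' 8 s of rest before the instruction screen) is subtracted, putting values
#' in Delta-% units. The pre-subtraction normalized values are retained as
#' assays `"leftNorm"`/`"rightNorm"` for the range filter.
#'
#' @inheritParams detectArtifacts
#' @return The baseline-corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, cfg = preprocessConfig()) {
  stopifnot(is(epochs, "EpochSet"))
  if (!isNormalized(epochs))
    stop("baseline correction requires normalized epochs")
  idx <- windowIdx(relTime(epochs), cfg@baselineWindow)
  if (length(idx) == 0L)
    stop("baseline window is empty on the epoch time grid")
  L <- assayL(epochs); R <- assayR(epochs)
  if (!isBaselineCorrected(epochs)) {
    SummarizedExperiment::assay(epochs, "leftNorm") <- L
    SummarizedExperiment::assay(epochs, "rightNorm") <- R
  }
  L <- sweep(L, 2, colMeans(L[idx, , drop = FALSE]))
  R <- sweep(R, 2, colMeans(R[idx, , drop = FALSE]))
  epochs <- setAssays(epochs, L, R)
  metaSet(epochs, "baselineCorrected", TRUE)
}

#' Reject epochs with out-of-range normalized velocity
#'
#' Any kept epoch containing a normalized sample strictly below
#' `cfg@rangeBounds[1]` (default 60%) or strictly above `rangeBounds[2]`
#' (default 140%) is marked `excluded_range`. Evaluated on the
#' pre-baseline-subtraction normalized values (assays
#' `"leftNorm"`/`"rightNorm"` when present), since the bounds are only
#' meaningful on the mean-100 scale.
#'
#' @inheritParams detectArtifacts
#' @return The filtered [EpochSet-class].
#' @export
rejectOutOfRange <- function(epochs, cfg = preprocessConfig()) {
  stopifnot(is(epochs, "EpochSet"))
  if (!isNormalized(epochs))
    stop("range rejection requires normalized epochs")
  an <- SummarizedExperiment::assayNames(epochs)
  L <- if ("leftNorm" %in% an)
    SummarizedExperiment::assay(epochs, "leftNorm") else assayL(epochs)
  R <- if ("rightNorm" %in% an)
    SummarizedExperiment::assay(epochs, "rightNorm") else assayR(epochs)
  lo <- cfg@rangeBounds[1]; hi <- cfg@rangeBounds[2]
  bad <- apply(L < lo | L > hi | R < lo | R > hi, 2, any)
  cd <- SummarizedExperiment::colData(epochs)
  hit <- bad & cd$qcStatus == "kept"
  SummarizedExperiment::colData(epochs)$qcStatus[hit] <- "excluded_range"
  epochs <- qcLogAppend(epochs, "epochsExcludedRange", sum(hit))
  if (!any(qcStatus(epochs) == "kept"))
    stop("insufficient epochs: all epochs rejected by quality control")
  epochs
}

#' Run the full preprocessing chain on a raw recording
#'
#' Applies, in order: down-sampling, epoching, manual exclusions, artifact
#' detection, normalization, heart-cycle integration, baseline correction
#' and range rejection.
#'
#' @inheritParams epochRecording
#' @param rec a raw [BilateralRecording-class] (any rate that is an integer
#'   multiple of `cfg@targetRate`).
#' @param manualExclusions design trial indices rejected by visual
#'   inspection (optional).
#' @return A quality-controlled, baseline-corrected [EpochSet-class].
#' @export
preprocessSession <- function(rec, sched, cfg = preprocessConfig(),
                              manualExclusions = integer(0)) {
  es <- epochRecording(downsample(rec, cfg@targetRate), sched, cfg)
  if (length(manualExclusions)) es <- excludeManually(es, manualExclusions)
  es <- detectArtifacts(es, cfg)
  es <- normalizeEpochs(es)
  es <- suppressWarnings(heartCycleIntegrate(es))
  es <- baselineCorrect(es, cfg)
  rejectOutOfRange(es, cfg)
}
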