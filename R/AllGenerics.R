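#' @rdname BilateralRecording-class
#' @param object,x a [BilateralRecording-class] or [EpochSet-class].
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname BilateralRecording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname EpochSet-class
#' @param x an [EpochSet-class].
#' @export
setGeneric("relTime", function(x) standardGeneric("relTime"))

#' @rdname EpochSet-class
#' @export
setGeneric("qcStatus", function(x) standardGeneric("qcStatus"))

#' @rdname EpochSet-class
#' @export
setGeneric("trialIndex", function(x) standardGeneric("trialIndex"))

#' @rdname EpochSet-class
#' @export
setGeneric("keptEpochs", function(x) standardGeneric("keptEpochs"))

#' @rdname EpochSet-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname EpochSet-class
#' @export
setGeneric("isBaselineCorrected",
           function(x) standardGeneric("isBaselineCorrected"))

setMethod("samplingRate", "BilateralRecording", function(x) x@samplingRate)
setMethod("duration", "BilateralRecording",
          function(x) length(x@left) / x@samplingRate)

#' @rdname BilateralRecording-class
#' @export
leftVelocity <- function(x) x@left

#' @rdname BilateralRecording-class
#' @export
rightVelocity <- function(x) x@right

setMethod("show", "BilateralRecording", function(object) {
  cat(sprintf("BilateralRecording: %d samples/channel at %g Hz (%.1f s)\n",
              length(object@left), object@samplingRate, duration(object)))
})

setMethod("show", "TaskSchedule", function(object) {
  cat(sprintf(
    "TaskSchedule: %d trials (instruction %g s, task %g s, rest %g s)\n",
    length(object@onsets), object@instructionDur, object@taskDur,
    object@restDur))
})

setMethod("samplingRate", "EpochSet",
          function(x) S4Vectors::metadata(x)$samplingRate)
setMethod("relTime", "EpochSet",
          function(x) SummarizedExperiment::rowData(x)$relTime)
setMethod("qcStatus", "EpochSet",
          function(x) SummarizedExperiment::colData(x)$qcStatus)
setMethod("trialIndex", "EpochSet",
          function(x) SummarizedExperiment::colData(x)$trialIndex)
setMethod("keptEpochs", "EpochSet", function(x) x[, qcStatus(x) == "kept"])
setMethod("isNormalized", "EpochSet",
          function(x) isTRUE(S4Vectors::metadata(x)$normalized))
setMethod("isBaselineCorrected", "EpochSet",
          function(x) isTRUE(S4Vectors::metadata(x)$baselineCorrected))

setMethod("show", "EpochSet", function(object) {
  st <- table(factor(qcStatus(object), levels = QC_LEVELS))
  cat(sprintf("EpochSet: %d epochs x %d samples at %g Hz\n",
              ncol(object), nrow(object), samplingRate(object)))
  cat(sprintf("  window [%g, %g] s; normalized: %s; baseline-corrected: %s\n",
              min(relTime(object)),
              max(relTime(object)) + 1 / samplingRate(object),
              isNormalized(object), isBaselineCorrected(object)))
  cat("  QC:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LateralityResult", function(object) {
  cat(sprintf("LateralityResult: LI = %.3f (SE %.3f), %d%% CI [%.3f, %.3f]\n",
              object@li, object@se, round(object@level * 100),
              object@ciLow, object@ciHigh))
  cat(sprintf("  n epochs = %d; split-half odd/even = %.3f / %.3f\n",
              object@nEpochs, object@liOdd, object@liEven))
  cat(sprintf("  classification: %s (dichotomous: %s)\n",
              object@label, object@dichotomous))
})

setMethod("show", "SessionSimConfig", function(object) {
  cat(sprintf(
    "SessionSimConfig: trait %g, state %g, noise sd %g%%, HR %g bpm, seed %g\n",
    object@traitLI, object@stateOffset, object@noiseSd, object@hrBpm,
    object@seed))
})
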