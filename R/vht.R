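#' Score visual half-field trials into per-hemifield accuracies
#'
#' Accuracy per visual hemifield among non-control trials. Central-fixation
#' control trials (`isControl`) never enter the asymmetry.
#'
#' @param trials data frame with columns `field` (`"LVF"`/`"RVF"`),
#'   `correct` (logical) and optionally `isControl` (logical).
#' @return List with `accLVF`, `accRVF`, `nLVF`, `nRVF`.
#' @export
scoreVHT <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("field", "correct") %in%
                                         names(trials)))
  if (!is.null(trials$isControl)) trials <- trials[!trials$isControl, ]
  if (!all(trials$field %in% c("LVF", "RVF")))
    stop("field must be 'LVF' or 'RVF'")
  lvf <- trials$field == "LVF"
  nL <- sum(lvf); nR <- sum(!lvf)
  if (nL == 0L || nR == 0L)
    stop("at least one non-control trial per hemifield is required")
  list(accLVF = mean(trials$correct[lvf]),
       accRVF = mean(trials$correct[!lvf]),
       nLVF = nL, nRVF = nR)
}

#' Visual half-field accuracy asymmetry
#'
#' Normalized accuracy difference `(accLVF - accRVF) / (accLVF + accRVF)`,
#' bounded in [-1, 1]. A right-visual-field advantage (left-hemisphere
#' language dominance) yields a negative value, matching the Doppler sign
#' convention (negative = leftward dominance).
#'
#' @param accLVF,accRVF per-hemifield accuracies in [0, 1].
#' @return Signed asymmetry index; `NA` when both accuracies are zero.
#' @examples
#' vhtAsymmetry(0.6, 0.9)  # -0.2
#' @export
vhtAsymmetry <- function(accLVF, accRVF) {
  stopifnot(accLVF >= 0, accLVF <= 1, accRVF >= 0, accRVF <= 1)
  s <- accLVF + accRVF
  if (s == 0) return(NA_real_)
  (accLVF - accRVF) / s
}

#' Reaction-time asymmetry (secondary index)
#'
#' Same normalized-difference form on median correct-trial reaction times,
#' sign inverted so that faster right-visual-field responses (left
#' dominance) come out negative, consistent with [vhtAsymmetry()].
#'
#' @param trials data frame as in [scoreVHT()] with an `rt_ms` column.
#' @return Signed asymmetry; `NA` if either field has no correct trial.
#' @export
vhtRTAsymmetry <- function(trials) {
  stopifnot(is.data.frame(trials), "rt_ms" %in% names(trials))
  if (!is.null(trials$isControl)) trials <- trials[!trials$isControl, ]
  trials <- trials[trials$correct & is.finite(trials$rt_ms), ]
  mL <- median(trials$rt_ms[trials$field == "LVF"])
  mR <- median(trials$rt_ms[trials$field == "RVF"])
  if (!is.finite(mL) || !is.finite(mR) || mL + mR == 0) return(NA_real_)
  -(mL - mR) / (mL + mR)
}
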