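#' Per-epoch laterality indices
#'
#' Mean over the period of interest of (right - left) baseline-corrected
#' normalized velocity, one value per kept epoch. Negative values indicate
#' leftward (left-hemisphere) dominance.
#'
#' @param epochs a baseline-corrected [EpochSet-class].
#' @param cfg a [PreprocessConfig-class] (supplies the POI window).
#' @return Named numeric vector, names = design trial indices.
#' @export
perEpochLI <- function(epochs, cfg = preprocessConfig()) {
  stopifnot(is(epochs, "EpochSet"))
  if (!isBaselineCorrected(epochs))
    stop("laterality requires baseline-corrected epochs")
  kept <- keptEpochs(epochs)
  idx <- windowIdx(relTime(kept), cfg@poiWindow)
  if (length(idx) == 0L) stop("POI window is empty on the epoch time grid")
  d <- assayR(kept)[idx, , drop = FALSE] - assayL(kept)[idx, , drop = FALSE]
  stats::setNames(colMeans(d), trialIndex(kept))
}

ciMultiplier <- function(method, n, level) {
  switch(method,
         t = if (n >= 2) qt(1 - (1 - level) / 2, df = n - 1) else NA_real_,
         normal = qnorm(1 - (1 - level) / 2),
         stop("unknown ciMethod: ", method))
}

#' Build a laterality result from per-epoch LIs
#'
#' The session LI is the mean of the per-epoch LIs; its standard error is
#' the sample (n-1) standard deviation over epochs divided by sqrt(n); the
#' confidence interval uses a t quantile on n-1 degrees of freedom by
#' default (`ciMethod = "normal"` gives the fixed 1.96-type multiplier).
#' Dominance is then classified with [classifyCI()].
#'
#' @param liPerEpoch per-epoch LIs; names, if present, are design trial
#'   indices used for the odd/even split.
#' @param ciMethod `"t"` (default) or `"normal"`.
#' @param level confidence level.
#' @return A [LateralityResult-class].
#' @export
lateralityFromEpochLIs <- function(liPerEpoch, ciMethod = c("t", "normal"),
                                   level = 0.95) {
  ciMethod <- match.arg(ciMethod)
  n <- length(liPerEpoch)
  if (n < 2L)
    stop("at least 2 kept epochs are required (SE undefined otherwise)")
  li <- mean(liPerEpoch)
  se <- sd(liPerEpoch) / sqrt(n)
  mult <- ciMultiplier(ciMethod, n, level)
  trial <- if (!is.null(names(liPerEpoch)))
    as.integer(names(liPerEpoch)) else seq_len(n)
  odd <- liPerEpoch[trial %% 2L == 1L]
  even <- liPerEpoch[trial %% 2L == 0L]
  res <- new("LateralityResult", li = li, se = se,
             ciLow = li - mult * se, ciHigh = li + mult * se,
             nEpochs = as.integer(n), perEpochLI = unname(liPerEpoch),
             liOdd = if (length(odd)) mean(odd) else NA_real_,
             liEven = if (length(even)) mean(even) else NA_real_,
             label = "BLD", dichotomous = "left",
             ciMethod = ciMethod, level = level)
  lab <- classifyCI(res)
  res@label <- lab$trichotomous
  res@dichotomous <- lab$dichotomous
  res
}

#' Compute the session laterality index
#'
#' @inheritParams perEpochLI
#' @inheritParams lateralityFromEpochLIs
#' @return A [LateralityResult-class] with LI, SE, confidence interval,
#'   split-half LIs and dominance labels.
#' @export
computeLI <- function(epochs, cfg = preprocessConfig(),
                      ciMethod = c("t", "normal"), level = 0.95) {
  lateralityFromEpochLIs(perEpochLI(epochs, cfg), match.arg(ciMethod), level)
}

#' Split-half laterality indices
#'
#' LIs computed separately over odd- and even-numbered design trials
#' (parity by original 1-based trial index, not post-QC position). An empty
#' half yields `NA` rather than an error.
#'
#' @inheritParams perEpochLI
#' @return List with elements `liOdd` and `liEven`.
#' @export
splitHalfLI <- function(epochs, cfg = preprocessConfig()) {
  pe <- perEpochLI(epochs, cfg)
  trial <- as.integer(names(pe))
  odd <- pe[trial %% 2L == 1L]
  even <- pe[trial %% 2L == 0L]
  list(liOdd = if (length(odd)) mean(odd) else NA_real_,
       liEven = if (length(even)) mean(even) else NA_real_)
}

#' Confidence-interval dominance classification
#'
#' Bilateral (`"BLD"`) when the confidence interval contains zero;
#' otherwise left (`"LLD"`) for negative LI, right (`"RLD"`) for positive.
#' The dichotomous label follows the sign of the LI; an LI of exactly zero
#' resolves to `"left"` with a warning (measure-zero tie-break).
#'
#' @param result a [LateralityResult-class], or a numeric LI when `ciLow`
#'   and `ciHigh` are given explicitly.
#' @param ciLow,ciHigh explicit confidence bounds (ignored when `result` is
#'   a [LateralityResult-class]).
#' @return List with elements `trichotomous` and `dichotomous`.
#' @export
classifyCI <- function(result, ciLow = NULL, ciHigh = NULL) {
  if (is(result, "LateralityResult")) {
    li <- result@li; ciLow <- result@ciLow; ciHigh <- result@ciHigh
  } else li <- result
  tri <- if (ciLow <= 0 && 0 <= ciHigh) "BLD"
         else if (li < 0) "LLD" else "RLD"
  if (li == 0 && !(se0 <- isTRUE(all.equal(c(ciLow, ciHigh), c(0, 0)))))
    warning("LI is exactly zero; dichotomous label resolved to 'left'")
  dich <- if (li > 0) "right" else "left"
  list(trichotomous = tri, dichotomous = dich)
}

#' Fixed-cutoff dominance classification
#'
#' Bilateral when `|li| <= cutoff`; otherwise by the sign of the LI.
#' Vectorized over `li`.
#'
#' @param li laterality indices.
#' @param cutoff non-negative cutoff in the LI's units.
#' @return Character vector of `"LLD"`, `"BLD"`, `"RLD"`.
#' @export
classifyCutoff <- function(li, cutoff) {
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 0)
    stop("cutoff must be a single non-negative number")
  ifelse(abs(li) <= cutoff, "BLD", ifelse(li < 0, "LLD", "RLD"))
}
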