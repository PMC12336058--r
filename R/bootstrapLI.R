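#' Configuration for the threshold-independent bootstrap laterality index
#'
#' @param nThresholds number of equally spaced threshold levels between 0
#'   (exclusive) and the maximum statistic value.
#' @param nBoot bootstrap resamples per side per threshold.
#' @param resampleRatio resample size as a fraction of the side's
#'   supra-threshold voxel count (sizes are rounded up).
#' @param trim fraction trimmed from each tail of the pairwise LI
#'   distribution before averaging (0.25 keeps the central 50%).
#' @param minVoxels minimum supra-threshold voxels for a side to count as
#'   active at a threshold.
#' @param seed integer RNG seed.
#' @param exhaustive enumerate all possible resamples instead of drawing
#'   `nBoot` random ones (tiny inputs only; makes the index deterministic
#'   and exactly antisymmetric under hemisphere swap).
#' @return List of class `"bootstrapLIConfig"`.
#' @export
bootstrapLIConfig <- function(nThresholds = 20, nBoot = 100,
                              resampleRatio = 0.25, trim = 0.25,
                              minVoxels = 5, seed = 1, exhaustive = FALSE) {
  stopifnot(resampleRatio > 0, resampleRatio <= 1, trim >= 0, trim < 0.5,
            nThresholds >= 1, nBoot >= 1, minVoxels >= 1)
  structure(list(nThresholds = nThresholds, nBoot = nBoot,
                 resampleRatio = resampleRatio, trim = trim,
                 minVoxels = minVoxels, seed = seed,
                 exhaustive = exhaustive),
            class = "bootstrapLIConfig")
}

# All size-k multisets drawn with replacement from n items, as a k x n^k
# index matrix (exhaustive analogue of the bootstrap resampling).
exhaustiveIdx <- function(n, k) {
  if (n^k > 2e5) stop("exhaustive enumeration too large (", n^k, " resamples)")
  m <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  t(m)
}

resampleSums <- function(values, cfg) {
  n <- length(values)
  if (n == 0L) return(0)
  k <- ceiling(cfg$resampleRatio * n)
  idx <- if (cfg$exhaustive) exhaustiveIdx(n, k)
         else matrix(sample.int(n, k * cfg$nBoot, replace = TRUE), nrow = k)
  if (k == 1L) values[idx[1, ]] else colSums(matrix(values[idx], nrow = k))
}

#' Threshold-independent bootstrap laterality index
#'
#' Computes a laterality index from two sets of region-of-interest voxel
#' statistics by sweeping a ladder of activation thresholds, bootstrapping
#' supra-threshold values on each side, forming all pairwise indices
#' `(sum(right) - sum(left)) / (sum(right) + sum(left))`, trimming the
#' tails, and combining per-threshold trimmed means with weights
#' proportional to the threshold level. The result lies in [-1, +1]:
#' -1 means activation only in the left hemisphere, +1 only in the right.
#'
#' A threshold is admissible when both sides retain at least
#' `cfg$minVoxels` supra-threshold voxels. When no threshold qualifies
#' (one-sided activation), thresholds where a single side qualifies are
#' used instead, with the inactive side contributing zero sums — which
#' pins the index to the exact -1/+1 endpoint.
#'
#' @param leftValues,rightValues voxel statistic values per hemisphere
#'   (only positive values count as activation).
#' @param cfg a [bootstrapLIConfig()].
#' @return List of class `"bootstrapLIResult"` with `liOverall`,
#'   `perThreshold` (data frame: `threshold`, `li`, `nLeft`, `nRight`),
#'   `nThresholdsUsed` and `config`.
#' @export
bootstrapLI <- function(leftValues, rightValues, cfg = bootstrapLIConfig()) {
  stopifnot(inherits(cfg, "bootstrapLIConfig"))
  leftValues <- leftValues[is.finite(leftValues)]
  rightValues <- rightValues[is.finite(rightValues)]
  mx <- max(c(leftValues, rightValues, 0))
  thresholds <- mx * seq_len(cfg$nThresholds) / cfg$nThresholds
  nL <- vapply(thresholds, function(th) sum(leftValues > th), 0L)
  nR <- vapply(thresholds, function(th) sum(rightValues > th), 0L)
  both <- nL >= cfg$minVoxels & nR >= cfg$minVoxels
  admissible <- if (any(both)) both
                else nL >= cfg$minVoxels | nR >= cfg$minVoxels
  oneSided <- !any(both)
  if (!any(admissible))
    stop("insufficient supra-threshold voxels: no admissible threshold")
  rows <- withSeed(cfg$seed, {
    lapply(which(admissible), function(i) {
      th <- thresholds[i]
      lv <- leftValues[leftValues > th]
      rv <- rightValues[rightValues > th]
      if (oneSided) {
        if (nL[i] < cfg$minVoxels) lv <- numeric(0)
        if (nR[i] < cfg$minVoxels) rv <- numeric(0)
      }
      sL <- resampleSums(lv, cfg)
      sR <- resampleSums(rv, cfg)
      li <- (rep(sR, each = length(sL)) - sL) /
            (rep(sR, each = length(sL)) + sL)
      data.frame(threshold = th, li = mean(li, trim = cfg$trim),
                 nLeft = nL[i], nRight = nR[i])
    })
  })
  pt <- do.call(rbind, rows)
  liOverall <- sum(pt$threshold * pt$li) / sum(pt$threshold)
  structure(list(liOverall = liOverall, perThreshold = pt,
                 nThresholdsUsed = nrow(pt), config = cfg),
            class = "bootstrapLIResult")
}

#' @export
print.bootstrapLIResult <- function(x, ...) {
  cat(sprintf("Bootstrap LI = %.3f over %d threshold(s)\n",
              x$liOverall, x$nThresholdsUsed))
  invisible(x)
}

#' Extract hemisphere ROI values from a statistic volume
#'
#' @param volume numeric array of statistic values.
#' @param maskLeft,maskRight logical arrays of the same shape; must be
#'   disjoint.
#' @return List with `leftValues` and `rightValues`.
#' @export
extractROIValues <- function(volume, maskLeft, maskRight) {
  if (!identical(dim(volume), dim(maskLeft)) ||
      !identical(dim(volume), dim(maskRight)))
    stop("volume and masks must have identical dimensions")
  if (any(maskLeft & maskRight)) stop("left and right masks overlap")
  list(leftValues = as.numeric(volume[maskLeft]),
       rightValues = as.numeric(volume[maskRight]))
}
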