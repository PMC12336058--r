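#' Intraclass correlation, two-way model, single measurement
#'
#' ICC from the two-way ANOVA decomposition of an n-subjects x k-sessions
#' table. The default (`type = "agreement"`, i.e. ICC(A,1)) penalizes
#' systematic between-session shifts:
#' \deqn{ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' Its F test of zero correlation uses `F = MSR/MSE` referred to an F
#' distribution whose denominator df is the Satterthwaite approximation of
#' the mixed mean square `a*MSC + b*MSE` (generally non-integer).
#' `type = "consistency"` gives ICC(C,1) with integer df.
#'
#' @param x an n x k numeric matrix (subjects x sessions) or a data frame
#'   whose columns are the sessions.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return List of class `"iccResult"` with `icc`, `f`, `df1`, `df2`, `p`,
#'   `msr`, `msc`, `mse`, `n`, `k`, `type`.
#' @examples
#' iccA1(cbind(c(1, 3, 5), c(2, 4, 6)))$icc  # 8/9
#' @export
iccA1 <- function(x, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("x must be complete and finite")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L || k < 2L) stop("need at least 3 subjects and 2 sessions")
  rowM <- rowMeans(x); colM <- colMeans(x); grand <- mean(x)
  ssTot <- sum((x - grand)^2)
  ssR <- k * sum((rowM - grand)^2)
  ssC <- n * sum((colM - grand)^2)
  ssE <- ssTot - ssR - ssC
  if (ssTot < 1e-12) stop("degenerate data: zero total variance")
  msr <- ssR / (n - 1)
  msc <- ssC / (k - 1)
  mse <- ssE / ((n - 1) * (k - 1))
  if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    f <- if (mse > 0) msr / mse else Inf
    # Satterthwaite df of the mixed mean square a*MSC + b*MSE, with the
    # ICC estimate plugged into a and b (yields non-integer df2)
    r0 <- min(icc, 1 - 1e-12)
    a <- (k * r0) / (n * (1 - r0))
    b <- 1 + (k * r0 * (n - 1)) / (n * (1 - r0))
    den <- a * msc + b * mse
    df2 <- if (den > 0)
      den^2 / ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    else (n - 1) * (k - 1)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- if (mse > 0) msr / mse else Inf
    df2 <- (n - 1) * (k - 1)
  }
  df1 <- n - 1
  p <- pf(f, df1, df2, lower.tail = FALSE)
  structure(list(icc = icc, f = f, df1 = df1, df2 = df2, p = p,
                 msr = msr, msc = msc, mse = mse, n = n, k = k, type = type),
            class = "iccResult")
}

#' @export
print.iccResult <- function(x, ...) {
  cat(sprintf("ICC (%s, single measurement) = %.3f, F(%g, %.1f) = %.3g, p = %.3g\n",
              x$type, x$icc, x$df1, x$df2, x$f, x$p))
  invisible(x)
}

#' Cohen's kappa for two categorical classifications
#'
#' Chance-corrected agreement over a fixed category universe (default the
#' trichotomous dominance labels, so absent categories still contribute
#' zero marginals). The Z statistic uses the large-sample null standard
#' error under chance agreement (Fleiss-type).
#'
#' @param labels1,labels2 equal-length label vectors.
#' @param levels category universe.
#' @return List of class `"kappaResult"` with `kappa`, `z`, `p` (one-sided,
#'   agreement beyond chance), `po`, `pe`, `contingency`, `n`.
#' @export
cohensKappa <- function(labels1, labels2,
                        levels = c("LLD", "BLD", "RLD")) {
  if (length(labels1) != length(labels2) || length(labels1) < 2L)
    stop("labels1 and labels2 must have equal length >= 2")
  f1 <- factor(labels1, levels = levels)
  f2 <- factor(labels2, levels = levels)
  if (anyNA(f1) || anyNA(f2)) stop("labels outside the category universe")
  tab <- table(f1, f2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  p1 <- rowSums(tab) / n
  p2 <- colSums(tab) / n
  pe <- sum(p1 * p2)
  if (1 - pe < 1e-12) {
    return(structure(list(kappa = NA_real_, z = NA_real_, p = NA_real_,
                          po = po, pe = pe, contingency = tab, n = n),
                     class = "kappaResult"))
  }
  kappa <- (po - pe) / (1 - pe)
  varNull <- (pe + pe^2 - sum(p1 * p2 * (p1 + p2))) / (n * (1 - pe)^2)
  z <- kappa / sqrt(varNull)
  structure(list(kappa = kappa, z = z, p = pnorm(z, lower.tail = FALSE),
                 po = po, pe = pe, contingency = tab, n = n),
            class = "kappaResult")
}

#' @export
print.kappaResult <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (Z = %.2f, p = %.3g), n = %d\n",
              x$kappa, x$z, x$p, x$n))
  invisible(x)
}

#' Percentage agreement between two classifications
#'
#' @param labels1,labels2 equal-length label vectors.
#' @param subset optional logical or integer subgroup selector.
#' @return List with `agree` (count), `n`, `ratio` (exact proportion) and
#'   `percent` (rounded to integer, as conventionally displayed).
#' @export
percentAgreement <- function(labels1, labels2, subset = NULL) {
  if (length(labels1) != length(labels2))
    stop("labels1 and labels2 must have equal length")
  if (!is.null(subset)) {
    labels1 <- labels1[subset]; labels2 <- labels2[subset]
  }
  n <- length(labels1)
  if (n == 0L) stop("empty subgroup")
  agree <- sum(labels1 == labels2)
  list(agree = agree, n = n, ratio = agree / n,
       percent = round(100 * agree / n))
}

#' Bland-Altman limits of agreement
#'
#' Per-subject session differences (`session1 - session2`) against their
#' means, with limits of agreement at mean difference +/- 1.96 sample
#' standard deviations of the differences.
#'
#' @param li1,li2 paired per-subject measurements from sessions 1 and 2.
#' @return List of class `"blandAltman"` with `meanDiff`, `sdDiff`,
#'   `loaLow`, `loaHigh`, and a `points` data frame (`mean`, `diff`) for
#'   plotting.
#' @export
blandAltman <- function(li1, li2) {
  if (length(li1) != length(li2) || length(li1) < 2L)
    stop("need paired vectors of equal length >= 2")
  d <- li1 - li2
  m <- (li1 + li2) / 2
  meanDiff <- mean(d)
  sdDiff <- sd(d)
  structure(list(meanDiff = meanDiff, sdDiff = sdDiff,
                 loaLow = meanDiff - 1.96 * sdDiff,
                 loaHigh = meanDiff + 1.96 * sdDiff,
                 points = data.frame(mean = m, diff = d)),
            class = "blandAltman")
}

#' @export
print.blandAltman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.3f, LoA [%.3f, %.3f] (sd %.3f)\n",
              x$meanDiff, x$loaLow, x$loaHigh, x$sdDiff))
  invisible(x)
}

#' Cut-off sweep of bilateral classification reliability
#'
#' For each cut-off, the proportion of subjects classified bilateral in
#' session 1 (`|li1| <= cutoff`) and, among those, the proportion also
#' bilateral in session 2 (`NA` when no subject is bilateral in session 1).
#'
#' @param li1,li2 paired per-subject LIs.
#' @param cutoffs non-negative, sorted cut-offs (default 0 to 1.5 in steps
#'   of 0.1).
#' @return Data frame with columns `cutoff`, `propBilateralS1`,
#'   `propReplicated`, `nBilateralS1`.
#' @export
cutoffSweep <- function(li1, li2, cutoffs = seq(0, 1.5, by = 0.1)) {
  if (any(cutoffs < 0) || is.unsorted(cutoffs))
    stop("cutoffs must be non-negative and sorted")
  if (length(li1) != length(li2)) stop("li1 and li2 must be paired")
  rows <- lapply(cutoffs, function(co) {
    b1 <- abs(li1) <= co
    nb <- sum(b1)
    data.frame(cutoff = co,
               propBilateralS1 = mean(b1),
               propReplicated = if (nb > 0) mean(abs(li2[b1]) <= co)
                                else NA_real_,
               nBilateralS1 = nb)
  })
  do.call(rbind, rows)
}

#' Welch, Student and paired t tests for group comparisons
#'
#' Thin wrapper over [stats::t.test()] (Welch df for unpaired, n-1 for
#' paired) that rejects degenerate zero-variance input with a clear error.
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired paired test?
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return The `htest` object from [stats::t.test()].
#' @export
groupTTest <- function(x, y, paired = FALSE,
                       alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (paired) {
    if (length(x) != length(y)) stop("paired test requires equal lengths")
    if (length(x) < 2L) stop("need at least 2 pairs")
    if (var(x - y) == 0)
      stop("zero variance of paired differences: t statistic undefined")
  } else {
    if (length(x) < 2L || length(y) < 2L)
      stop("need at least 2 observations per group")
    if (var(x) == 0 && var(y) == 0)
      stop("zero variance in both groups: t statistic undefined")
  }
  t.test(x, y, paired = paired, alternative = alternative, var.equal = FALSE)
}

# Null distribution of the Mann-Whitney U statistic by exhaustive
# enumeration of which ranks belong to the first sample (handles ties via
# midranks). Returns the U values of all C(n1+n2, n1) assignments.
mwEnumerate <- function(r, n1) {
  n <- length(r)
  sel <- combn(n, n1)
  apply(sel, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
}

#' One- or two-sided Mann-Whitney U test with effect size
#'
#' Reports the rank-sum statistic in the same convention as
#' [stats::wilcox.test()] (`W = U` of the first sample, i.e. the number of
#' pairs with `x > y`, ties counting one half). The p value is obtained by
#' exhaustive enumeration of the permutation null when
#' `min(n1, n2) <= 8` and `n1 + n2 <= 20`, and otherwise by the normal
#' approximation with tie and continuity corrections. The effect size is
#' `r = |z| / sqrt(n1 + n2)` with `z` from the (tie-corrected) normal
#' approximation.
#'
#' @param x,y numeric samples.
#' @param alternative `"less"` (x tends smaller), `"greater"` or
#'   `"two.sided"`.
#' @return List of class `"rankTest"` with `statistic` (W), `p`, `z`,
#'   `effectR`, `method`, `n1`, `n2`.
#' @export
mannWhitneyU <- function(x, y, alternative = c("less", "greater",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tieTab <- table(r)
  tieAdj <- sum(tieTab^3 - tieTab) / ((n1 + n2) * (n1 + n2 - 1))
  sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tieAdj)
  sigma <- sqrt(sigma2)
  cc <- if (sigma > 0) 0.5 else 0
  z <- if (sigma > 0) {
    switch(alternative,
           less = (U - mu + cc) / sigma,
           greater = (U - mu - cc) / sigma,
           two.sided = (U - mu - sign(U - mu) * cc) / sigma)
  } else 0
  exact <- min(n1, n2) <= 8 && (n1 + n2) <= 20
  if (exact) {
    null <- mwEnumerate(r, n1)
    p <- switch(alternative,
                less = mean(null <= U),
                greater = mean(null >= U),
                two.sided = min(1, 2 * min(mean(null <= U),
                                           mean(null >= U))))
  } else {
    p <- switch(alternative,
                less = pnorm(z),
                greater = pnorm(z, lower.tail = FALSE),
                two.sided = 2 * pnorm(-abs(z)))
  }
  structure(list(statistic = U, p = p, z = z,
                 effectR = min(1, abs(z) / sqrt(n1 + n2)),
                 method = if (exact) "exact enumeration"
                          else "normal approximation",
                 n1 = n1, n2 = n2, alternative = alternative),
            class = "rankTest")
}

#' @export
print.rankTest <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: W = %g, p = %.4g (%s, %s), r = %.3f\n",
              x$statistic, x$p, x$alternative, x$method, x$effectR))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Wrapper over [stats::cor.test()] with average ranks for ties and the
#' t-approximation p value. Constant input yields an `NA` correlation
#' rather than an error.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return List with `rho`, `p`, `n`.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
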