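test_that("ICC(A,1) reproduces the hand-ANOVA worked example", {
  x <- cbind(c(1, 3, 5), c(2, 4, 6))
  r <- iccA1(x)
  expect_equal(r$msr, 8)
  expect_equal(r$msc, 1.5)
  expect_equal(r$mse, 0, tolerance = 1e-12)
  expect_equal(r$icc, 8 / 9, tolerance = 1e-9)
  expect_equal(r$df1, 2)

  # perfect agreement
  expect_equal(iccA1(cbind(c(1, 2, 4), c(1, 2, 4)))$icc, 1)
  expect_error(iccA1(cbind(c(1, 1, 1), c(1, 1, 1))), "degenerate")
  expect_error(iccA1(cbind(1:2, 1:2)), "at least 3")
})

test_that("ICC mean squares agree with an independent aov decomposition", {
  set.seed(101)
  n <- 12
  x <- matrix(rnorm(n * 2, sd = 2), n, 2) + rnorm(n, sd = 3)
  r <- iccA1(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(n), 2)),
                   sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = df))[[1]][, "Mean Sq"]
  expect_equal(r$msr, ms[1], tolerance = 1e-8)
  expect_equal(r$msc, ms[2], tolerance = 1e-8)
  expect_equal(r$mse, ms[3], tolerance = 1e-8)
  k <- 2
  expect_equal(r$icc,
               (ms[1] - ms[3]) /
                 (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3])),
               tolerance = 1e-8)
  # Satterthwaite denominator df is generally non-integer and positive
  expect_gt(r$df2, 0)
  expect_false(isTRUE(all.equal(r$df2, round(r$df2))))
})

test_that("absolute agreement penalizes a session shift; consistency does not", {
  set.seed(7)
  s1 <- rnorm(30, sd = 2)
  x <- cbind(s1, s1 + 1.5)  # pure additive retest shift
  expect_lt(iccA1(x, "agreement")$icc, iccA1(x, "consistency")$icc)
  expect_equal(iccA1(x, "consistency")$icc, 1, tolerance = 1e-9)
})

test_that("ICC approaches the closed-form variance ratio at large n", {
  set.seed(55)
  n <- 600
  subj <- rnorm(n, sd = sqrt(3))
  x <- cbind(subj + rnorm(n), subj + rnorm(n))
  expect_equal(iccA1(x)$icc, 0.75, tolerance = 0.05)
})

test_that("Cohen's kappa matches hand-computed tables", {
  # perfect agreement on two categories
  l <- rep(c("A", "B"), times = c(10, 10))
  expect_equal(cohensKappa(l, l, levels = c("A", "B"))$kappa, 1)

  # [[20, 5], [10, 15]]: po 0.7, pe 0.5, kappa 0.4
  l1 <- rep(c("A", "A", "B", "B"), times = c(20, 5, 10, 15))
  l2 <- rep(c("A", "B", "A", "B"), times = c(20, 5, 10, 15))
  r <- cohensKappa(l1, l2, levels = c("A", "B"))
  expect_equal(r$po, 0.7)
  expect_equal(r$pe, 0.5)
  expect_equal(r$kappa, 0.4, tolerance = 1e-12)
  expect_gt(r$z, 0)

  # independence
  l1i <- rep(c("A", "A", "B", "B"), times = c(5, 5, 5, 5))
  l2i <- rep(c("A", "B", "A", "B"), times = c(5, 5, 5, 5))
  expect_equal(cohensKappa(l1i, l2i, levels = c("A", "B"))$kappa, 0)

  # invariant under consistent relabelling
  rl <- c(A = "RLD", B = "LLD")
  r2 <- cohensKappa(rl[l1], rl[l2])
  expect_equal(r2$kappa, r$kappa, tolerance = 1e-12)

  # single shared category: kappa undefined, not an error
  expect_true(is.na(cohensKappa(rep("BLD", 5), rep("BLD", 5))$kappa))

  # the fixed trichotomous universe tolerates absent categories
  expect_s3_class(cohensKappa(c("LLD", "BLD", "LLD"),
                              c("LLD", "LLD", "LLD")), "kappaResult")
})

test_that("percentage agreement reports exact ratios and display rounding", {
  l1 <- rep("BLD", 35)
  l2 <- rep(c("BLD", "LLD", "RLD"), times = c(18, 16, 1))
  r <- percentAgreement(l1, l2)
  expect_equal(r$agree, 18)
  expect_equal(r$ratio, 18 / 35)
  expect_equal(r$percent, 51)
  expect_equal(percentAgreement(l1, l1)$percent, 100)
  expect_error(percentAgreement(l1, l2, rep(FALSE, 35)), "empty subgroup")
})

test_that("Bland-Altman limits of agreement are mean +/- 1.96 sd", {
  r0 <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$meanDiff, 0)
  expect_equal(r0$sdDiff, 0)
  expect_equal(c(r0$loaLow, r0$loaHigh), c(0, 0))

  # differences {1, -1, 1, -1}
  r <- blandAltman(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(r$meanDiff, 0)
  expect_equal(r$sdDiff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(r$loaHigh, 2.263, tolerance = 1e-3)
  expect_equal(r$loaHigh - r$meanDiff, 1.96 * r$sdDiff)

  # ~95% of Gaussian differences fall inside the limits
  set.seed(31)
  a <- rnorm(2000); b <- a + rnorm(2000)
  rg <- blandAltman(a, b)
  inside <- mean(rg$points$diff > rg$loaLow & rg$points$diff < rg$loaHigh)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("cutoff sweep enumerates bilateral proportions monotonically", {
  sw <- cutoffSweep(c(-0.05, -2, 0.3), c(-0.2, -2.1, -0.4))
  expect_equal(sw$cutoff, seq(0, 1.5, 0.1))
  expect_equal(nrow(sw), 16L)
  at05 <- sw[abs(sw$cutoff - 0.5) < 1e-9, ]
  expect_equal(at05$propBilateralS1, 2 / 3)
  expect_equal(at05$nBilateralS1, 2L)
  # both session-2 LIs of the session-1 bilaterals are within 0.5
  expect_equal(at05$propReplicated, 1)
  # cutoff 0 with no exact zeros: nobody is bilateral, replication undefined
  expect_equal(sw$propBilateralS1[1], 0)
  expect_true(is.na(sw$propReplicated[1]))
  # monotone in the cutoff
  expect_true(all(diff(sw$propBilateralS1) >= 0))

  set.seed(9)
  li1 <- rnorm(40); li2 <- rnorm(40)
  sw2 <- cutoffSweep(li1, li2, seq(0, 3, 0.25))
  expect_true(all(diff(sw2$propBilateralS1) >= 0))
  expect_error(cutoffSweep(li1, li2, c(0.5, 0.1)), "sorted")
})

test_that("group t tests cover Welch, paired and degenerate inputs", {
  r0 <- groupTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p.value, 1)

  rp <- groupTTest(c(1, 2, 3), c(2, 3, 5), paired = TRUE)
  expect_equal(abs(unname(rp$statistic)), 4, tolerance = 1e-9)
  expect_equal(unname(rp$parameter), 2)
  expect_equal(rp$p.value, 2 * pt(-4, 2), tolerance = 1e-9)
  expect_equal(rp$p.value, 0.0572, tolerance = 1e-3)

  expect_error(groupTTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
               "zero variance")
})

test_that("Mann-Whitney exact enumeration and approximation agree with
           references", {
  # C(5,2) = 10 equally likely rank assignments; only {1,2} gives U = 0
  r <- mannWhitneyU(c(1, 2), c(3, 4, 5), alternative = "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$method, "exact enumeration")

  # cross-check exact p against wilcox.test on tie-free draws
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(7)
    for (alt in c("less", "greater", "two.sided")) {
      expect_equal(mannWhitneyU(x, y, alt)$p,
                   stats::wilcox.test(x, y, alternative = alt)$p.value,
                   tolerance = 1e-10)
    }
  }

  # exchangeable samples: near-null p, negligible effect size
  re <- mannWhitneyU(c(1, 2, 3, 4), c(1, 2, 3, 4), alternative = "less")
  expect_gt(re$p, 0.4)
  expect_lt(re$effectR, 0.2)

  # exact and normal-approximation p values stay within 0.02 at n = 8 + 8
  set.seed(77)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    r <- mannWhitneyU(x, y, alternative = "less")
    expect_equal(r$method, "exact enumeration")
    expect_lt(abs(r$p - pnorm(r$z)), 0.02)
  }

  # large samples switch to the tie-corrected normal approximation
  set.seed(5)
  rl <- mannWhitneyU(rnorm(30), rnorm(30) + 1, alternative = "less")
  expect_equal(rl$method, "normal approximation")
  expect_lt(rl$p, 0.05)
  expect_true(rl$effectR >= 0 && rl$effectR <= 1)
})

test_that("Spearman correlation handles monotone, tied and constant input", {
  expect_equal(spearmanRho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanRho(c(1, 2, 3), c(3, 1, 2))$rho, -0.5, tolerance = 1e-9)
  expect_equal(spearmanRho(1:8, -(1:8))$rho, -1)
  expect_true(is.na(spearmanRho(rep(1, 5), 1:5)$rho))
  # agreement with cor() on ranks under ties
  set.seed(3)
  x <- sample(1:5, 20, replace = TRUE)
  y <- x + sample(0:2, 20, replace = TRUE)
  expect_equal(spearmanRho(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-9)
})
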