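---
title: "Measuring hemispheric dominance from bilateral blood-flow velocity: methods and design choices"
author: "DopplerLI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doppler laterality methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DopplerLI)
```

## The measurement problem

Functional transcranial Doppler sonography (fTCDS) records cerebral blood
flow velocity (CBFV) simultaneously in the left and right middle cerebral
arteries while a participant performs a lateralized cognitive task —
here, covert letter-cued word generation. Because task-evoked neural
activity raises perfusion in the hemisphere doing the work, the
velocity difference between the two arteries indexes hemispheric
dominance. DopplerLI implements the full chain from raw two-channel
recordings to a laterality index (LI) with uncertainty, a dominance
classification, a test–retest reliability battery, and companion
asymmetry measures for behavioural (visual half-field) and fMRI
(region-of-interest statistic map) data.

Throughout the package, **negative values mean leftward (left-hemisphere)
dominance**: the Doppler LI is the mean of (right − left) velocity
responses, behavioural asymmetry is (LVF − RVF)/(LVF + RVF) on accuracies
(a right-visual-field advantage projects to the left hemisphere), and the
bootstrap fMRI index is (ΣR − ΣL)/(ΣR + ΣL), running from −1 (activation
only on the left) to +1 (only on the right).

## The preprocessing chain

`preprocessSession()` applies, in order:

1. **Down-sampling** (`downsample()`): block averaging from the native
   rate (100 Hz) to the analysis rate (25 Hz). Non-overlapping block means
   double as an anti-aliasing filter, are exactly testable, and are
   adequate for the smooth CBFV envelope.
2. **Epoching** (`epochRecording()`): 38 s windows per trial, from 10 s
   before the instruction-screen onset to 28 s after it. The trial itself
   occupies 3 s (instruction) + 20 s (word generation) = 23 s; the window
   therefore carries the full 10 s pre-stimulus rest and 5 s of
   post-task padding. Placing the padding after the task is the only
   arrangement that preserves the stated pre-window inside a 38 s epoch.
3. **Spike/dropout handling** (`detectArtifacts()`): per channel, the
   0.0001 and 0.9999 quantiles of all epoched samples of the session
   delimit physiologically implausible values. The quantiles are taken at
   session level deliberately — at ~950 samples a per-epoch 10^-4^
   quantile would be meaningless. Within an epoch (counting both
   channels): one outlier is replaced by the mean of its epoch-channel
   computed *excluding* the outlier (a 10× spike must not drag its own
   replacement); two or more exclude the epoch, the paper-world unit of
   rejection. Note a literal reading of the quantile rule has a
   deliberate consequence: on a 16-trial session (15 200 samples/channel)
   the interpolated type-7 quantiles always sit just inside the two most
   extreme samples per tail, so a handful of genuine extremes are
   "corrected" even in clean data. This is the published rule as stated,
   and its effect on the LI is negligible (≤1 sample in 425 per POI).
4. **Normalization** (`normalizeEpochs()`): each channel is divided by its
   session-level mean over kept epochs and multiplied by 100, removing
   insonation-angle and vessel-diameter differences. Session-level (not
   per-epoch) means keep the subsequent 60–140% range filter meaningful;
   per-epoch normalization would force every epoch mean to 100 and
   largely disable it.
5. **Heart-cycle integration** (`heartCycleIntegrate()`): cardiac
   pulsatility is removed by replacing each cardiac cycle with its
   time-mean. Cycles are delimited by diastolic troughs — local minima at
   least 0.33 s apart (≤180 bpm). Trough positions are refined to
   sub-sample precision by parabolic interpolation and each cycle mean is
   a trapezoidal integral with fractional end-points; at 25 Hz a naive
   sample-to-sample mean leaves ~1% ripple because the cardiac period is
   a non-integer number of samples, while the refined construction keeps
   residual ripple well below 0.5% on a 20%-amplitude pulse. Windows with
   fewer than two detected troughs (e.g. constant signals) pass through
   unchanged and are flagged.
6. **Baseline correction** (`baselineCorrect()`): the mean of the 8 s of
   rest preceding the instruction screen is subtracted per epoch and
   channel, yielding Δ% units. Subtraction (not division) keeps the LI on
   the additive scale on which group means of ≈ −3 Δ% are interpretable.
   The pre-subtraction normalized values are retained.
7. **Range rejection** (`rejectOutOfRange()`): epochs containing
   normalized samples strictly below 60% or strictly above 140% of the
   channel mean are excluded, evaluated on the retained pre-subtraction
   values — the bounds are only meaningful on the mean-100 scale. The
   comparison is strict: 60.0 and 140.0 survive.

All windows are half-open `[from, to)` on the sample grid, which makes
the 17 s period of interest exactly 425 samples at 25 Hz and the 8 s
baseline exactly 200, with no double-counted boundary sample.
Visual-inspection rejections are supported only as an externally supplied
trial list (`excludeManually()`); they are never automated.

## Laterality index, uncertainty and classification

For each kept epoch, `perEpochLI()` averages (right − left) over the
period of interest — 6 s to 23 s after instruction onset, i.e. from 3 s
into word generation to its end, when the evoked response has plateaued.
The session LI is the mean of the per-epoch LIs, its standard error the
sample (n−1) standard deviation over epochs divided by √n, and the 95%
confidence interval `li ± q · se`.

**Choice of the CI multiplier.** With ~16 epochs, the multiplier matters.
The package defaults to the *t* quantile on n−1 degrees of freedom
(`ciMethod = "t"`, q ≈ 2.13 at n = 16), with the fixed normal multiplier
(≈1.96) available as `ciMethod = "normal"`. The reason is coverage: for
Gaussian epoch noise the 1.96·SE interval covers the true LI with
probability P(|t₁₅| ≤ 1.96) ≈ 0.93, so a "95%" interval built with 1.96
mislabels ~7% of truly symmetric sessions as lateralized. The t interval
achieves nominal coverage, which the calibration test verifies: across
1 000 simulated sessions with zero true laterality, the share classified
bilateral falls inside the 95% binomial band around 0.95.

`classifyCI()` labels a session bilateral (BLD) exactly when the CI
contains zero, otherwise left (LLD) or right (RLD) by the LI's sign. The
dichotomous label follows the sign alone; an LI of exactly zero — a
measure-zero event needing a deterministic rule — resolves to "left" with
a warning. `classifyCutoff()` implements the alternative fixed-threshold
scheme (|LI| ≤ cutoff ⇒ bilateral). Split-half LIs use odd/even parity of
the *original* 1-based trial indices, not post-QC positions: "odd trials"
names design positions, which keeps the halves comparable across subjects
with different exclusions.

## The reliability battery

`runReliability()` bundles the statistics used to quantify test–retest
reliability of LIs and their classifications:

* **ICC(A,1)** (`iccA1()`): two-way model, absolute agreement, single
  measurement, from the ANOVA decomposition
  (MS~R~ − MS~E~) / (MS~R~ + (k−1)MS~E~ + (k/n)(MS~C~ − MS~E~)).
  Absolute agreement (rather than consistency) is the right choice for
  retest data because it penalizes systematic between-session shifts. The
  zero-ICC F test refers MS~R~/MS~E~ to an F distribution whose
  denominator df is the Satterthwaite approximation for the mixed mean
  square a·MS~C~ + b·MS~E~ — generally non-integer, as in the common
  two-way agreement implementations.
* **Cohen's kappa** (`cohensKappa()`): chance-corrected agreement over
  the fixed {LLD, BLD, RLD} universe, so absent categories contribute
  zero marginals; Z from the Fleiss large-sample null standard error.
* **Percentage agreement** (`percentAgreement()`): stored as an exact
  ratio, displayed rounded to integer percent.
* **Bland–Altman** (`blandAltman()`): session1 − session2 differences
  against pair means, limits of agreement at ±1.96 sample sd of the
  differences. The difference direction is arbitrary and fixed for
  determinism.
* **Cut-off sweep** (`cutoffSweep()`): proportion bilateral in session 1
  and its replication in session 2 over cut-offs 0 … 1.5 in steps of 0.1;
  both proportions are non-decreasing in the cut-off by construction.
* **Group tests**: `groupTTest()` (Welch or paired, via `stats::t.test`),
  `mannWhitneyU()` and `spearmanRho()`. The Mann–Whitney p value is an
  exhaustive permutation enumeration when min(n₁,n₂) ≤ 8 and n₁+n₂ ≤ 20
  (exact even under ties, via midranks), otherwise the tie- and
  continuity-corrected normal approximation. The reported effect size is
  r = |z|/√N with z from the normal approximation — the most common
  convention, stated explicitly because the literature rarely defines it.

## Visual half-field asymmetry

`scoreVHT()` computes per-hemifield accuracy over non-control trials;
`vhtAsymmetry()` forms (acc~LVF~ − acc~RVF~)/(acc~LVF~ + acc~RVF~),
bounded in [−1, 1], reaching an endpoint only when one field's accuracy
is zero, and strictly monotone in each argument. The normalized
difference was chosen over the raw difference because absolute-value
group comparisons need an index whose scale does not depend on overall
accuracy. A reaction-time variant (`vhtRTAsymmetry()`, sign-inverted so
faster right-field responses come out negative) is provided as a
secondary measure.

## Threshold-independent bootstrap LI for statistic maps

`bootstrapLI()` sweeps `nThresholds` (20) equally spaced levels from just
above 0 to the map maximum. At each admissible threshold it draws
`nBoot` (100) bootstrap resamples of size ⌈0.25·n⌉ per hemisphere from
the supra-threshold values, forms all nBoot² pairwise indices
(ΣR − ΣL)/(ΣR + ΣL), trims 25% from each tail, and keeps the trimmed
mean; the overall index is the threshold-weighted mean (weights
proportional to the threshold level, emphasising high, specific
thresholds). All parameters are exposed in `bootstrapLIConfig()`.

**Admissibility.** A threshold normally requires at least `minVoxels` (5)
supra-threshold voxels in *both* hemispheres. When no threshold
qualifies — a genuinely one-sided map — the fall-back uses thresholds
where a single hemisphere qualifies and lets the inactive side contribute
zero sums, which pins the index to exactly −1 or +1, matching the
stated range semantics (−1 = activation only in the left hemisphere).
Without the fall-back, one-sided maps would be an error; without the
both-sides primary rule, high thresholds that strip one hemisphere of
nearly (but not exactly) all voxels would drag two-sided maps towards the
endpoints.

An `exhaustive = TRUE` mode enumerates every possible resample on tiny
inputs, making the index deterministic and exactly antisymmetric under
hemisphere swap — the form used by the symmetry tests. The index is
exactly invariant under positive rescaling of the map, since the
threshold ladder scales with the maximum.

## The synthetic-data generator

`simulateSession()` generates each channel as

baseline · (1 + pulsatility) · (1 + (response + noise)/100)

* **Trait/state/noise structure.** The evoked response amplitude
  (default 4%) is split antisymmetrically: left gets A − d/2, right
  A + d/2, with d = `traitLI` (a stable, person-specific asymmetry) +
  `stateOffset` (a session-specific shift). The pipeline's LI therefore
  estimates d directly, which is what makes parameter-recovery tests
  sharp. `retestCohortConfig()` draws traits from a two-component
  Gaussian mixture — a dominant leftward mode (mean −3, sd 1, weight
  0.85) and a near-zero minority (mean 0, sd 0.5, weight 0.15) — chosen
  to mimic the shape of verbal-fluency LI distributions (a large
  left-lateralized mode plus a small weakly-lateralized group); the
  numbers are simulation conventions, not population estimates. State
  offsets are independent Normal(0, `stateSd`) per session; no
  quantitative state variance is established in the literature, so
  `stateSd` has a conventional default of 0.8 Δ%.
* **Response shape.** The response ramps linearly from task onset,
  reaches its plateau `responseOnsetLag` (3 s) later — a standard
  hemodynamic latency — and decays symmetrically after task end. Because
  the plateau covers the whole period of interest, the POI mean of the
  response profile is exactly 1 and the expected recovered LI equals d
  without shape-induced attenuation. A convolved canonical response was
  deliberately avoided: the POI-mean LI is insensitive to the exact
  shape, and the piecewise-linear form gives closed-form expectations.
* **What is *not* exact.** Normalization divides each channel by its own
  session mean, which includes part of the evoked response; at d = −3
  this attenuates the recovered LI by ≈4% (expected ≈ −2.88 rather than
  −3.00). The recovery tests use the ±0.3 band with this attenuation
  understood. The measurement-noise contribution to the LI's
  between-session variance has no clean closed form after the nonlinear
  QC chain, so it is characterized empirically from a zero-trait,
  zero-state calibration batch and inserted into the variance-ratio
  prediction trait²/(trait² + state² + σ²~m~) for the cohort ICC check.
* **Pulsatility and noise.** Cardiac pulsatility is a three-harmonic
  zero-mean waveform at `hrBpm` (70) with relative amplitude
  `pulsatilityFrac` (0.25 — realistic systolic/diastolic velocity
  swings); measurement noise is AR(1) (coefficient 0.9 at 100 Hz,
  stationary sd 1%). Spikes (brief ×3 bursts, 0.04 s) and dropouts
  (×0.1, 0.2 s) are injected at per-minute rates and/or explicit times,
  and every injected event is recorded in the truth ledger.
* **What the generator does not emulate**: detailed cardiac waveform
  physiology (Windkessel dynamics), insonation-depth or probe-gain
  effects, respiratory and CO₂ oscillations, or slow drifts in vessel
  diameter. Passing tests therefore demonstrate correctness of the
  analysis chain under a plausible signal model, not robustness to every
  artifact class of real recordings.

All stochastic functions take explicit integer seeds, restore the
caller's RNG state, and reproduce outputs bit-for-bit under identical
configuration.

## Numerical conventions and degenerate inputs

* Quantile bounds use R's default type-7 interpolation; outlier
  comparisons are strict, as are the 60/140 range bounds.
* Down-sampling requires an integer rate ratio and rejects anything else.
* Fewer than two kept epochs is an error (the SE is undefined); an empty
  split-half is `NA`, not an error.
* Zero total variance is an error for the ICC ("degenerate data") and the
  t tests; a single shared category makes kappa `NA`; constant input
  makes Spearman's ρ `NA`.
* `classifyCutoff(li, 0)` labels only an exact zero bilateral.
* The bootstrap LI errors when neither hemisphere ever reaches
  `minVoxels` supra-threshold voxels.

## Problem sizes used by the verification suite

The simulation-backed checks use 1 000 sessions for the CI-classifier
calibration, 50 sessions for trait recovery at −3, a 200-subject
two-session cohort (trait sd 2, state sd 0.8) for the ICC-versus-theory
comparison, and 200 replications for the visual half-field power check —
sizes chosen so that Monte-Carlo error is comfortably below the decision
bands being tested.

## Known limitations

* The heart-cycle integrator assumes troughs are the most reliable
  landmark; severe dropouts inside a cycle can distort that cycle's mean
  (such epochs are usually excluded by the artifact or range filters
  first).
* The exact ICC F-test convention (Satterthwaite df with the estimate
  plugged in) matches the common two-way agreement implementations, but
  other packages print other df pairs; the ICC value itself is unaffected.
* The Mann–Whitney effect size convention r = |z|/√N is one of several in
  use; comparisons across reports should check the convention.
* The bootstrap LI's threshold-weighted mean emphasises high thresholds;
  maps whose weaker hemisphere barely clears `minVoxels` at high
  thresholds can sit noticeably beyond the raw sum-ratio of the means.
  This is inherent to threshold-weighted laterality and not a bug.
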