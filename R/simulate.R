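# Task-evoked response time course: for each trial, a ramp from task onset
# reaching 1 at task onset + lag, a plateau until task end, and a symmetric
# decay. The plateau covers the whole period of interest, so the POI mean
# of the response is exactly 1 and the generator's laterality split
# propagates to the pipeline LI without shape-induced attenuation.
responseCourse <- function(t, sched, lag) {
  r <- numeric(length(t))
  for (o in sched@onsets) {
    up0 <- o + sched@instructionDur
    dn0 <- o + sched@instructionDur + sched@taskDur
    i <- which(t >= up0 & t < dn0 + lag)
    ti <- t[i]
    r[i] <- pmin(1, (ti - up0) / lag, (dn0 + lag - ti) / lag)
  }
  r
}

ar1Noise <- function(n, sdStat, phi) {
  if (sdStat == 0) return(numeric(n))
  as.numeric(filter(rnorm(n, 0, sdStat * sqrt(1 - phi^2)), phi,
                    method = "recursive"))
}

# Cardiac waveform with harmonics, zero mean over whole cycles.
pulseWave <- function(t, hrBpm) {
  f <- hrBpm / 60
  sin(2 * pi * f * t) + 0.5 * sin(4 * pi * f * t + 0.8) +
    0.25 * sin(6 * pi * f * t + 1.6)
}

#' Simulate a bilateral word-generation session
#'
#' Generates a two-channel velocity recording under the trait/state/noise
#' model: each channel is
#' `baseline * (1 + pulsatility) * (1 + (response + noise) / 100)`, where
#' the task-evoked response amplitude is split antisymmetrically across
#' hemispheres — left gets `responseAmplitude - d/2`, right
#' `responseAmplitude + d/2` with `d = traitLI + stateOffset` — so the
#' laterality recovered by the preprocessing pipeline (right minus left
#' convention) equals `d` up to normalization attenuation and noise.
#' Optional spikes (brief multiplicative bursts) and dropouts (brief
#' signal losses) are injected at the configured per-minute rates and/or
#' explicit times.
#'
#' @param cfg a [sessionSimConfig()].
#' @return List with `recording` ([BilateralRecording-class]), `schedule`
#'   ([TaskSchedule-class]) and `truth` — a list recording `traitLI`,
#'   `stateOffset`, `expectedLI` (their sum) and an `artifacts` data frame
#'   (`time`, `channel`, `type`).
#' @export
simulateSession <- function(cfg) {
  stopifnot(is(cfg, "SessionSimConfig"))
  sched <- cfg@schedule
  rate <- cfg@samplingRate
  dur <- max(sched@onsets) + sched@instructionDur + sched@taskDur + 10
  n <- as.integer(round(dur * rate))
  t <- (seq_len(n) - 1L) / rate
  d <- cfg@traitLI + cfg@stateOffset
  ampL <- cfg@responseAmplitude - d / 2
  ampR <- cfg@responseAmplitude + d / 2
  r <- responseCourse(t, sched, cfg@responseOnsetLag)
  puls <- 1 + cfg@pulsatilityFrac * pulseWave(t, cfg@hrBpm)
  out <- withSeed(cfg@seed, {
    epsL <- ar1Noise(n, cfg@noiseSd, cfg@noiseAR)
    epsR <- ar1Noise(n, cfg@noiseSd, cfg@noiseAR)
    left <- cfg@baselineLeft * puls * (1 + (ampL * r + epsL) / 100)
    right <- cfg@baselineRight * puls * (1 + (ampR * r + epsR) / 100)
    nSpike <- rpois(1, cfg@spikeRate * dur / 60)
    nDrop <- rpois(1, cfg@dropoutRate * dur / 60)
    art <- data.frame(
      time = c(runif(nSpike, 0, dur - 0.1), cfg@spikeTimes,
               runif(nDrop, 0, dur - 0.3), cfg@dropoutTimes),
      channel = sample(c("left", "right"),
                       nSpike + nDrop + length(cfg@spikeTimes) +
                         length(cfg@dropoutTimes), replace = TRUE),
      type = rep(c("spike", "dropout"),
                 c(nSpike + length(cfg@spikeTimes),
                   nDrop + length(cfg@dropoutTimes))))
    if (nrow(art)) {
      for (i in seq_len(nrow(art))) {
        span <- if (art$type[i] == "spike") 0.04 else 0.2
        idx <- seq(floor(art$time[i] * rate) + 1,
                   min(n, floor((art$time[i] + span) * rate)))
        fac <- if (art$type[i] == "spike") 3 else 0.1
        if (art$channel[i] == "left") left[idx] <- left[idx] * fac
        else right[idx] <- right[idx] * fac
      }
    }
    list(left = left, right = right, art = art)
  })
  list(recording = bilateralRecording(out$left, out$right, rate),
       schedule = sched,
       truth = list(traitLI = cfg@traitLI, stateOffset = cfg@stateOffset,
                    expectedLI = d, artifacts = out$art, seed = cfg@seed))
}

#' Configuration for a simulated retest cohort
#'
#' The trait laterality distribution is a two-component Gaussian mixture
#' emulating the shape seen in verbal-fluency cohorts: a dominant
#' left-lateralized mode plus a near-zero minority. The defaults are
#' simulation conventions, not population estimates.
#'
#' @param nSubjects number of subjects.
#' @param traitMeans,traitSds,traitWeights mixture components of the trait
#'   LI distribution (defaults: mean -3 sd 1 weight 0.85; mean 0 sd 0.5
#'   weight 0.15).
#' @param stateSd between-session state sd (Delta-%).
#' @param sessions sessions per subject.
#' @param template a [sessionSimConfig()] supplying everything except
#'   trait, state and seed.
#' @param seed integer seed; per-session seeds are derived from it.
#' @return List of class `"retestCohortConfig"`.
#' @export
retestCohortConfig <- function(nSubjects, traitMeans = c(-3, 0),
                               traitSds = c(1, 0.5),
                               traitWeights = c(0.85, 0.15),
                               stateSd = 0.8, sessions = 2,
                               template = sessionSimConfig(), seed = 1) {
  if (abs(sum(traitWeights) - 1) > 1e-9)
    stop("mixture weights must sum to 1")
  stopifnot(length(traitMeans) == length(traitSds),
            length(traitMeans) == length(traitWeights),
            stateSd >= 0, nSubjects >= 1, sessions >= 1)
  structure(list(nSubjects = nSubjects, traitMeans = traitMeans,
                 traitSds = traitSds, traitWeights = traitWeights,
                 stateSd = stateSd, sessions = sessions,
                 template = template, seed = seed),
            class = "retestCohortConfig")
}

cohortTruthTable <- function(cfg) {
  withSeed(cfg$seed, {
    comp <- sample.int(length(cfg$traitWeights), cfg$nSubjects,
                       replace = TRUE, prob = cfg$traitWeights)
    trait <- rnorm(cfg$nSubjects, cfg$traitMeans[comp], cfg$traitSds[comp])
    state <- matrix(rnorm(cfg$nSubjects * cfg$sessions, 0, cfg$stateSd),
                    nrow = cfg$nSubjects)
    seeds <- matrix(sample.int(2^30, cfg$nSubjects * cfg$sessions),
                    nrow = cfg$nSubjects)
    list(component = comp, trait = trait, state = state, seeds = seeds)
  })
}

sessionConfigFor <- function(cfg, truth, i, s) {
  tpl <- cfg$template
  tpl@traitLI <- truth$trait[i]
  tpl@stateOffset <- truth$state[i, s]
  tpl@seed <- truth$seeds[i, s]
  tpl
}

#' Simulate a paired-session retest cohort
#'
#' One trait draw per subject; one independent state offset per session;
#' sessions generated via [simulateSession()]. Intended for small cohorts
#' whose raw recordings are needed — for reliability studies at scale use
#' [simulateRetestLIs()], which streams sessions through the pipeline and
#' keeps only the recovered laterality results.
#'
#' @param cfg a [retestCohortConfig()].
#' @return List with `subjects` (per subject: `trait`, `component`, and a
#'   `sessions` list of [simulateSession()] outputs) and `config`.
#' @export
simulateRetestCohort <- function(cfg) {
  stopifnot(inherits(cfg, "retestCohortConfig"))
  truth <- cohortTruthTable(cfg)
  subjects <- lapply(seq_len(cfg$nSubjects), function(i) {
    sessions <- lapply(seq_len(cfg$sessions), function(s)
      simulateSession(sessionConfigFor(cfg, truth, i, s)))
    list(trait = truth$trait[i], component = truth$component[i],
         sessions = sessions)
  })
  list(subjects = subjects, config = cfg)
}

#' Simulate a retest cohort and recover laterality through the pipeline
#'
#' Generates each session, runs the full preprocessing chain and
#' [computeLI()], and discards the raw recordings.
#'
#' @param cfg a [retestCohortConfig()].
#' @param preprocCfg a [PreprocessConfig-class].
#' @param ciMethod passed to [computeLI()].
#' @return Data frame with one row per subject-session: `id`, `session`,
#'   `traitLI`, `stateOffset`, `expectedLI`, `li`, `se`, `nEpochs`,
#'   `label`, `component`.
#' @export
simulateRetestLIs <- function(cfg, preprocCfg = preprocessConfig(),
                              ciMethod = "t") {
  stopifnot(inherits(cfg, "retestCohortConfig"))
  truth <- cohortTruthTable(cfg)
  rows <- vector("list", cfg$nSubjects * cfg$sessions)
  k <- 0L
  for (i in seq_len(cfg$nSubjects)) {
    for (s in seq_len(cfg$sessions)) {
      sim <- simulateSession(sessionConfigFor(cfg, truth, i, s))
      es <- preprocessSession(sim$recording, sim$schedule, preprocCfg)
      res <- computeLI(es, preprocCfg, ciMethod = ciMethod)
      k <- k + 1L
      rows[[k]] <- data.frame(
        id = i, session = s, traitLI = truth$trait[i],
        stateOffset = truth$state[i, s],
        expectedLI = truth$trait[i] + truth$state[i, s],
        li = res@li, se = res@se, nEpochs = res@nEpochs,
        label = res@label, component = truth$component[i])
    }
  }
  do.call(rbind, rows)
}

#' Simulate visual half-field trials
#'
#' Counterbalanced design: each target word appears once in each hemifield;
#' correctness is Bernoulli with a per-field probability. Optional central
#' fixation-control trials are interleaved.
#'
#' @param nPerField target trials per hemifield.
#' @param pLVF,pRVF probability of a correct response per hemifield.
#' @param nControl number of control trials.
#' @param seed integer seed.
#' @return Data frame with columns `trial_index`, `word`, `field`,
#'   `correct`, `isControl`, `rt_ms`.
#' @export
simulateVHTTrials <- function(nPerField, pLVF, pRVF, nControl = 0,
                              seed = 1) {
  stopifnot(pLVF >= 0, pLVF <= 1, pRVF >= 0, pRVF <= 1)
  withSeed(seed, {
    words <- sprintf("w%03d", seq_len(nPerField))
    df <- data.frame(
      word = c(words, words, sprintf("digit%d", seq_len(nControl))),
      field = c(rep("LVF", nPerField), rep("RVF", nPerField),
                rep("CTR", nControl)),
      isControl = rep(c(FALSE, TRUE), c(2 * nPerField, nControl)))
    df <- df[sample.int(nrow(df)), ]
    p <- ifelse(df$field == "LVF", pLVF, ifelse(df$field == "RVF", pRVF, 1))
    df$correct <- runif(nrow(df)) < p
    df$rt_ms <- round(rnorm(nrow(df), 650, 80))
    df$trial_index <- seq_len(nrow(df))
    rownames(df) <- NULL
    df[, c("trial_index", "word", "field", "correct", "isControl", "rt_ms")]
  })
}

#' Simulate hemisphere ROI statistic values
#'
#' Gaussian voxel statistics truncated at zero ("activation"); a
#' non-positive mean produces an inactive hemisphere (all zeros). The
#' asymptotic sum-ratio laterality for positive means is
#' `(meanRight - meanLeft) / (meanRight + meanLeft)`.
#'
#' @param nPerSide voxels per hemisphere.
#' @param meanLeft,meanRight mean statistic value per hemisphere.
#' @param noiseSd voxel-to-voxel sd.
#' @param seed integer seed.
#' @return List with `leftValues`, `rightValues` and `truth` (the
#'   asymptotic LI, `NA` when undefined).
#' @export
simulateStatMap <- function(nPerSide, meanLeft, meanRight, noiseSd = 1,
                            seed = 1) {
  gen <- function(m) {
    if (m <= 0) rep(0, nPerSide) else pmax(rnorm(nPerSide, m, noiseSd), 0)
  }
  withSeed(seed, {
    lv <- gen(meanLeft)
    rv <- gen(meanRight)
    truth <- if (meanLeft <= 0 && meanRight <= 0) NA_real_
             else (max(meanRight, 0) - max(meanLeft, 0)) /
                  (max(meanRight, 0) + max(meanLeft, 0))
    list(leftValues = lv, rightValues = rv, truth = truth)
  })
}
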