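requireColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("malformed ", what, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Read a bilateral recording from CSV
#'
#' Expects columns `time_s`, `left_cmps`, `right_cmps` (header required).
#' The sampling rate is inferred from the time column, which must be
#' uniformly spaced; when `expectedRate` is given it is validated against
#' the inferred rate.
#'
#' @param path CSV file path.
#' @param expectedRate optional rate (Hz) to validate against.
#' @return A [BilateralRecording-class].
#' @export
readRecording <- function(path, expectedRate = NULL) {
  df <- requireColumns(read.csv(path), c("time_s", "left_cmps", "right_cmps"),
                       "recording CSV")
  dt <- diff(df$time_s)
  if (length(dt) < 1L) stop("recording CSV has fewer than 2 samples")
  if (max(abs(dt - dt[1])) > 1e-6)
    stop("time column is not uniformly spaced")
  rate <- 1 / median(dt)
  if (!is.null(expectedRate) && abs(rate - expectedRate) > 1e-6 * expectedRate)
    stop("sampling rate mismatch: file has ", signif(rate, 6),
         " Hz, expected ", expectedRate, " Hz")
  bilateralRecording(df$left_cmps, df$right_cmps, rate)
}

#' Write a bilateral recording to CSV
#'
#' @param rec a [BilateralRecording-class].
#' @param path output CSV path.
#' @export
writeRecording <- function(rec, path) {
  n <- length(leftVelocity(rec))
  df <- data.frame(time_s = (seq_len(n) - 1L) / samplingRate(rec),
                   left_cmps = leftVelocity(rec),
                   right_cmps = rightVelocity(rec))
  write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
}

#' Read a task schedule from CSV
#'
#' Expects columns `trial_index`, `onset_s`, `letter`.
#'
#' @param path CSV file path.
#' @param instructionDur,taskDur,restDur trial-phase durations (s).
#' @return A [TaskSchedule-class].
#' @export
readSchedule <- function(path, instructionDur = 3, taskDur = 20,
                         restDur = 15) {
  df <- requireColumns(read.csv(path), c("trial_index", "onset_s", "letter"),
                       "schedule CSV")
  df <- df[order(df$trial_index), ]
  taskSchedule(df$onset_s, instructionDur, taskDur, restDur, df$letter)
}

#' @rdname readSchedule
#' @param sched a [TaskSchedule-class] to write.
#' @export
writeSchedule <- function(sched, path) {
  write.csv(data.frame(trial_index = seq_along(sched@onsets),
                       onset_s = sched@onsets, letter = sched@letters),
            path, row.names = FALSE, quote = FALSE)
}

#' Read a preprocessing configuration from JSON
#'
#' @param path JSON file whose fields mirror the [preprocessConfig()]
#'   arguments; absent fields take the defaults.
#' @return A [PreprocessConfig-class].
#' @export
readPreprocessConfig <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- js[intersect(names(js), names(formals(preprocessConfig)))]
  do.call(preprocessConfig, args)
}

#' Export an epoch set to long-format CSV plus a QC summary
#'
#' Writes one row per (trial, channel, time point) with the epoch's QC
#' status, and a JSON summary of epoch counts per exclusion reason.
#'
#' @param epochs an [EpochSet-class].
#' @param path output CSV path.
#' @param qcPath optional JSON path for the QC summary.
#' @export
writeEpochSet <- function(epochs, path, qcPath = NULL) {
  rt <- relTime(epochs)
  cd <- SummarizedExperiment::colData(epochs)
  long <- do.call(rbind, lapply(seq_len(ncol(epochs)), function(j) {
    data.frame(trial_index = cd$trialIndex[j],
               channel = rep(c("left", "right"), each = length(rt)),
               rel_time_s = rt,
               value = c(assayL(epochs)[, j], assayR(epochs)[, j]),
               qc_status = cd$qcStatus[j])
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(qcPath)) {
    counts <- as.list(table(factor(cd$qcStatus, levels = QC_LEVELS)))
    jsonlite::write_json(c(counts, S4Vectors::metadata(epochs)$qcLog),
                         qcPath, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a paired-session cohort CSV
#'
#' Expects columns `id`, `li_s1`, `li_s2`; `label_s1`/`label_s2` are
#' recomputed from the LI sign and a `cutoff` when absent. Subjects with a
#' missing session are dropped with a message.
#'
#' @param path CSV file path.
#' @return Data frame of complete paired subjects.
#' @export
readCohort <- function(path) {
  df <- requireColumns(read.csv(path), c("id", "li_s1", "li_s2"),
                       "cohort CSV")
  ok <- complete.cases(df[, c("li_s1", "li_s2")])
  if (any(!ok))
    message(sum(!ok), " subject(s) with a missing session dropped")
  df[ok, ]
}

#' Run the full single-session analysis
#'
#' Reads (or accepts) a recording and schedule, applies the preprocessing
#' chain and computes the laterality result. Per-stage epoch counts are
#' reported via `message()`.
#'
#' @param recording a [BilateralRecording-class] or a recording CSV path.
#' @param schedule a [TaskSchedule-class] or a schedule CSV path.
#' @param cfg a [PreprocessConfig-class] or a JSON config path.
#' @param manualExclusions trial indices rejected by visual inspection.
#' @param ciMethod passed to [computeLI()].
#' @param jsonOut optional path to write the session report as JSON.
#' @return A [LateralityResult-class].
#' @export
runSession <- function(recording, schedule, cfg = preprocessConfig(),
                       manualExclusions = integer(0), ciMethod = "t",
                       jsonOut = NULL) {
  if (is.character(recording)) recording <- readRecording(recording)
  if (is.character(schedule)) schedule <- readSchedule(schedule)
  if (is.character(cfg)) cfg <- readPreprocessConfig(cfg)
  es <- preprocessSession(recording, schedule, cfg, manualExclusions)
  st <- table(factor(qcStatus(es), levels = QC_LEVELS))
  message("epochs: ", paste(names(st), st, sep = "=", collapse = ", "))
  res <- computeLI(es, cfg, ciMethod = ciMethod)
  if (!is.null(jsonOut)) {
    jsonlite::write_json(list(
      li = res@li, se = res@se, ci = c(res@ciLow, res@ciHigh),
      n_epochs = res@nEpochs, li_odd = res@liOdd, li_even = res@liEven,
      label_trichotomous = res@label, label_dichotomous = res@dichotomous,
      ci_method = res@ciMethod,
      qc = as.list(st),
      provenance = list(package = "DopplerLI",
                        version = as.character(packageVersion("DopplerLI")))),
      jsonOut, auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Run the test-retest reliability battery on a paired cohort
#'
#' Computes the ICC (absolute agreement), Cohen's kappa over the
#' trichotomous labels, percentage agreement for the whole cohort and the
#' initial-BLD/initial-LLD subgroups, dichotomous (sign) agreement and
#' sign-change counts, Bland-Altman limits of agreement, and the cut-off
#' sweep.
#'
#' @param cohort a data frame with columns `id`, `li_s1`, `li_s2` and
#'   optionally `label_s1`, `label_s2` — or a cohort CSV path.
#' @param cutoffs cut-off grid for [cutoffSweep()].
#' @return List of class `"analysisReport"`.
#' @export
runReliability <- function(cohort, cutoffs = seq(0, 1.5, by = 0.1)) {
  if (is.character(cohort)) cohort <- readCohort(cohort)
  requireColumns(cohort, c("id", "li_s1", "li_s2"), "cohort data")
  if (is.null(cohort$label_s1) || is.null(cohort$label_s2))
    stop("cohort must carry label_s1 and label_s2 (CI-based labels)")
  l1 <- cohort$label_s1; l2 <- cohort$label_s2
  sign1 <- ifelse(cohort$li_s1 < 0, "left", "right")
  sign2 <- ifelse(cohort$li_s2 < 0, "left", "right")
  sub <- function(lab) l1 == lab
  agreeIf <- function(mask) if (any(mask))
    percentAgreement(l1, l2, mask) else NULL
  iccIf <- function(mask) if (sum(mask) >= 3)
    iccA1(cbind(cohort$li_s1, cohort$li_s2)[mask, , drop = FALSE]) else NULL
  rep <- list(
    n = nrow(cohort),
    icc = iccA1(cbind(cohort$li_s1, cohort$li_s2)),
    iccBLD = iccIf(sub("BLD")),
    iccLLD = iccIf(sub("LLD")),
    kappa = cohensKappa(l1, l2),
    agreement = percentAgreement(l1, l2),
    agreementBLD = agreeIf(sub("BLD")),
    agreementLLD = agreeIf(sub("LLD")),
    dichotomousAgreement = percentAgreement(sign1, sign2),
    signChanged = sum(sign1 != sign2),
    blandAltman = blandAltman(cohort$li_s1, cohort$li_s2),
    cutoffSweep = cutoffSweep(cohort$li_s1, cohort$li_s2, cutoffs),
    provenance = list(package = "DopplerLI",
                      version = as.character(packageVersion("DopplerLI")),
                      date = format(Sys.Date())))
  class(rep) <- "analysisReport"
  rep
}

#' @export
print.analysisReport <- function(x, ...) {
  cat("Test-retest reliability report (n =", x$n, ")\n")
  print(x$icc)
  print(x$kappa)
  cat(sprintf("Whole-group agreement: %d%% (%d/%d)\n",
              x$agreement$percent, x$agreement$agree, x$agreement$n))
  if (!is.null(x$agreementBLD))
    cat(sprintf("Initial-BLD agreement: %d%% (%d/%d)\n",
                x$agreementBLD$percent, x$agreementBLD$agree,
                x$agreementBLD$n))
  if (!is.null(x$agreementLLD))
    cat(sprintf("Initial-LLD agreement: %d%% (%d/%d)\n",
                x$agreementLLD$percent, x$agreementLLD$agree,
                x$agreementLLD$n))
  cat(sprintf("Dichotomous (sign) agreement: %d%% (%d/%d); sign changed: %d\n",
              x$dichotomousAgreement$percent, x$dichotomousAgreement$agree,
              x$dichotomousAgreement$n, x$signChanged))
  print(x$blandAltman)
  invisible(x)
}

#' Write a simulated cohort to the pipeline's file formats
#'
#' Generates a retest cohort and writes one recording CSV per
#' subject-session, one shared schedule CSV, and a truth-ledger JSON.
#' Re-running with the same configuration reproduces byte-identical files.
#'
#' @param cfg a [retestCohortConfig()].
#' @param outDir output directory (created if needed).
#' @return Invisibly, the truth-ledger path.
#' @export
simulateToFiles <- function(cfg, outDir) {
  stopifnot(inherits(cfg, "retestCohortConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  truth <- cohortTruthTable(cfg)
  ledger <- list()
  writeSchedule(cfg$template@schedule, file.path(outDir, "schedule.csv"))
  for (i in seq_len(cfg$nSubjects)) {
    for (s in seq_len(cfg$sessions)) {
      sim <- simulateSession(sessionConfigFor(cfg, truth, i, s))
      f <- sprintf("sub%03d_ses%d.csv", i, s)
      writeRecording(sim$recording, file.path(outDir, f))
      ledger[[f]] <- sim$truth[c("traitLI", "stateOffset", "expectedLI",
                                 "seed")]
    }
  }
  ledgerPath <- file.path(outDir, "truth.json")
  jsonlite::write_json(ledger, ledgerPath, auto_unbox = TRUE, digits = NA)
  invisible(ledgerPath)
}

#' Read hemisphere statistic values from one-column text files
#'
#' @param leftPath,rightPath files with one statistic value per line (no
#'   header).
#' @return List with `leftValues`, `rightValues`.
#' @export
readStatValues <- function(leftPath, rightPath) {
  list(leftValues = scan(leftPath, quiet = TRUE),
       rightValues = scan(rightPath, quiet = TRUE))
}

#' Read a statistic volume and hemisphere masks from NIfTI files
#'
#' Optional volumetric plumbing for [bootstrapLI()]; requires the RNifti
#' package.
#'
#' @param volumePath statistic-map NIfTI; `maskLeftPath`, `maskRightPath`
#'   hemisphere masks (non-zero = inside).
#' @param maskLeftPath,maskRightPath mask NIfTI paths.
#' @return List with `leftValues`, `rightValues` (via [extractROIValues()]).
#' @export
readStatMapNIfTI <- function(volumePath, maskLeftPath, maskRightPath) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("readStatMapNIfTI requires the RNifti package")
  vol <- as.array(RNifti::readNifti(volumePath))
  ml <- as.array(RNifti::readNifti(maskLeftPath)) != 0
  mr <- as.array(RNifti::readNifti(maskRightPath)) != 0
  extractROIValues(vol, ml, mr)
}
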