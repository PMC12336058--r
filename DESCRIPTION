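Package: DopplerLI
Title: Laterality Indices from Bilateral Cerebral Blood Flow Velocity Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying hemispheric language dominance from
    functional transcranial Doppler sonography (fTCDS) and related
    modalities. Implements the full preprocessing chain for bilateral
    cerebral blood flow velocity recordings (down-sampling, epoching,
    spike/dropout handling, normalization, heart-cycle integration,
    baseline correction, range-based epoch rejection), laterality-index
    computation with epoch-wise standard errors and confidence-interval
    based dominance classification, a test-retest reliability battery
    (ICC with absolute agreement, Cohen's kappa, percentage agreement,
    Bland-Altman limits of agreement, cut-off sweeps, rank tests), visual
    half-field accuracy asymmetry scoring, a threshold-independent
    bootstrap laterality index for region-of-interest statistic maps, and
    a synthetic-data generator with an explicit trait/state/noise model of
    functional asymmetry for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
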