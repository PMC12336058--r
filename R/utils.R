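# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards. All stochastic functions route through this so
# identical configs give bit-identical output without disturbing user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Half-open window [from, to) on a relative time grid; returns row indices.
windowIdx <- function(relTime, window) {
  which(relTime >= window[1] - 1e-9 & relTime < window[2] - 1e-9)
}

assayL <- function(x) SummarizedExperiment::assay(x, "left")
assayR <- function(x) SummarizedExperiment::assay(x, "right")

setAssays <- function(x, left, right) {
  SummarizedExperiment::assay(x, "left") <- left
  SummarizedExperiment::assay(x, "right") <- right
  x
}

metaSet <- function(x, name, value) {
  S4Vectors::metadata(x)[[name]] <- value
  x
}

qcLogAppend <- function(x, name, value) {
  log <- S4Vectors::metadata(x)$qcLog
  log[[name]] <- value
  metaSet(x, "qcLog", log)
}
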