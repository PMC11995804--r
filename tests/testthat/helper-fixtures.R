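# Shared fixtures, built lazily and cached for the session.
# Small geometries keep the suite fast; fs must exceed twice the upper
# band edge of the planted sources (38 Hz), hence fs >= 96 throughout.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

tinySpec <- function(...) {
  args <- utils::modifyList(
    list(nProg = 6, nStable = 5, nSensors = 12, nEpochs = 1,
         epochLenS = 4, fs = 96, seed = 42,
         missingCounts = list(education = 2, mmse = 1, mri = 2)),
    list(...))
  do.call(cohortSpec, args)
}

# a mid-size planted cohort with all four metrics, reused by the
# stacking and risk tests
smallPlantedCohort <- function() {
  cached("planted", function() {
    spec <- cohortSpec(nProg = 33, nStable = 27, nSensors = 16,
                       nEpochs = 2, epochLenS = 5, fs = 96, seed = 41,
                       missingCounts = list(education = 8, mmse = 3,
                                            mri = 7))
    coh <- injectMissingness(simulateCohort(spec))
    fam <- buildWaveletFamily(4, 40, 0.35, 0.4, 96)
    tens <- suppressWarnings(
      lapply(cohortTable(coh)$subject_id, function(id)
        spectralFeatures(subjectSignals(coh, id), fam,
                         coh@layout@sensorIds)))
    list(coh = coh, tab = cohortTable(coh), tens = tens,
         foi = tens[[1]]@foi, fam = fam)
  })
}

randomSpd <- function(d, df = 2 * d) {
  Z <- matrix(rnorm(df * d), df, d)
  crossprod(Z) / df
}

spdArray <- function(n, d, df = 2 * d) {
  arr <- array(0, c(n, d, d))
  for (i in seq_len(n)) arr[i, , ] <- randomSpd(d, df)
  arr
}
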