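#' @import methods
#' @importFrom stats rnorm runif rbinom sd var cor quantile median
#'   pnorm pt pchisq p.adjust predict coef vcov binomial glm glm.control
#'   chisq.test wilcox.test ecdf fft mvfft nextn filter complete.cases
#' @importFrom utils head write.csv read.csv
#' @useDynLib megprog, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Sensor layout for a simulated magnetometer array
#'
#' Positions live on the unit disc (a flattened helmet view); the
#' posterior mask marks the parieto-occipital sensor set and the
#' adjacency relation drives spatial clustering in TFCE tests.
#'
#' @slot sensorIds character vector of sensor labels.
#' @slot positions numeric matrix (sensors x 2) of 2-D coordinates.
#' @slot posteriorMask logical vector, TRUE for parieto-occipital sensors.
#' @slot adjacency logical sensor x sensor matrix, symmetric with empty
#'   diagonal.
#' @exportClass SensorLayout
setClass("SensorLayout",
  representation(
    sensorIds = "character",
    positions = "matrix",
    posteriorMask = "logical",
    adjacency = "matrix"
  )
)

setValidity("SensorLayout", function(object) {
  n <- length(object@sensorIds)
  msg <- character(0)
  if (nrow(object@positions) != n || ncol(object@positions) != 2)
    msg <- c(msg, "positions must be sensors x 2")
  if (length(object@posteriorMask) != n)
    msg <- c(msg, "posteriorMask length mismatch")
  A <- object@adjacency
  if (!is.logical(A) || nrow(A) != n || ncol(A) != n)
    msg <- c(msg, "adjacency must be logical sensors x sensors")
  else {
    if (!identical(A, t(A))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A))) msg <- c(msg, "adjacency diagonal must be empty")
    if (any(rowSums(A) < 2)) msg <- c(msg, "each sensor needs >= 2 neighbours")
  }
  if (!any(object@posteriorMask))
    msg <- c(msg, "posteriorMask must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic two-site MCI cohort
#'
#' Default parameters reproduce the cohort structure assumed throughout
#' the pipeline: 64 progressors and 53 stable patients unevenly split
#' over two acquisition sites (CTB 41/49, CBU 23/4), group-specific
#' demographic and MRI distributions, planted spectral effects, and the
#' observed missingness pattern (15 education, 5 MMSE, 13 whole MRI
#' blocks).
#'
#' @slot nProg,nStable group sizes.
#' @slot siteTable 2 x 2 integer matrix, rows CTB/CBU, columns
#'   progression/stable.
#' @slot demographics list with per-group mean/sd (and clip range) for
#'   age, education, MMSE, plus male proportion.
#' @slot mriParams list with hippocampal-ratio mean/sd per group, total
#'   grey matter mean/sd, and regional-volume mean/sd (64 regions).
#' @slot effectSizes list: betaPowerReduction (fractional 16-38 Hz
#'   posterior amplitude drop in progressors), lowfreqCovShift,
#'   alphaPlvShift, envCorrShift.
#' @slot missingCounts list: education, mmse, mri.
#' @slot nEpochs,epochLenS,fs,nSensors signal geometry (12 x 10 s at
#'   250 Hz on 102 sensors by default, i.e. 2 min of data).
#' @slot seed integer master seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nProg = "numeric", nStable = "numeric",
    siteTable = "matrix",
    demographics = "list", mriParams = "list",
    effectSizes = "list", missingCounts = "list",
    nEpochs = "numeric", epochLenS = "numeric",
    fs = "numeric", nSensors = "numeric", seed = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nProg + object@nStable != sum(object@siteTable))
    msg <- c(msg, "nProg + nStable must equal sum(siteTable)")
  if (any(object@siteTable < 0)) msg <- c(msg, "siteTable counts must be >= 0")
  if (abs(object@fs * object@epochLenS -
          round(object@fs * object@epochLenS)) > 1e-9)
    msg <- c(msg, "fs * epochLenS must be an integer number of samples")
  es <- unlist(object@effectSizes)
  if (any(!is.finite(es))) msg <- c(msg, "effect sizes must be finite")
  b <- object@effectSizes$betaPowerReduction
  if (b < 0 || b > 1) msg <- c(msg, "betaPowerReduction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A simulated (or loaded) cohort: table + epoched signals + layout
#'
#' @slot table one row per subject: subject_id, group, site, sex, age,
#'   education, mmse, mri columns (hippocampal_ratio, total_grey_matter,
#'   vol_1..vol_64).
#' @slot signals named list of epochs x sensors x samples arrays.
#' @slot layout the [SensorLayout-class] used for projection.
#' @slot spec the generating [CohortSpec-class].
#' @exportClass MEGCohort
setClass("MEGCohort",
  representation(
    table = "data.frame",
    signals = "list",
    layout = "SensorLayout",
    spec = "CohortSpec"
  )
)

setValidity("MEGCohort", function(object) {
  msg <- character(0)
  if (length(object@signals) &&
      !identical(names(object@signals), object@table$subject_id))
    msg <- c(msg, "signals must be named by subject_id in table order")
  if (any(is.na(object@table$group)))
    msg <- c(msg, "group labels must never be missing")
  ok <- !is.na(object@table$mmse)
  if (any(object@table$mmse[ok] < 0 | object@table$mmse[ok] > 30))
    msg <- c(msg, "mmse must lie in [0, 30] when present")
  if (length(msg)) msg else TRUE
})

#' Family of log2-spaced Morlet wavelets
#'
#' Centre frequencies sit on a base-2 logarithmic grid; the Gaussian
#' envelope is parameterized so the half-power spectral edges of the
#' kernel at frequency f fall at f * 2^(+-bandwidthOct/2).
#'
#' @slot foi centre frequencies (Hz), strictly increasing.
#' @slot fMin,fMax,bandwidthOct,samplingOct,fs grid parameters.
#' @slot kernels list of complex time-domain kernels (unit spectral
#'   peak gain).
#' @slot validHalfwidth integer vector, samples to discard at each
#'   epoch edge per frequency (kernel truncation halfwidth).
#' @slot neb noise-equivalent bandwidth per kernel (Hz), used to scale
#'   mean squared coefficients to density units^2/Hz.
#' @exportClass WaveletFamily
setClass("WaveletFamily",
  representation(
    foi = "numeric", fMin = "numeric", fMax = "numeric",
    bandwidthOct = "numeric", samplingOct = "numeric", fs = "numeric",
    kernels = "list", validHalfwidth = "integer", neb = "numeric"
  )
)

setValidity("WaveletFamily", function(object) {
  msg <- character(0)
  foi <- object@foi
  if (any(diff(foi) <= 0)) msg <- c(msg, "foi must be strictly increasing")
  if (length(foi) > 1) {
    steps <- diff(log2(foi))
    if (any(abs(steps - object@samplingOct) > 1e-9))
      msg <- c(msg, "log2 spacing must equal samplingOct")
  }
  expected <- round(log2(object@fMax / object@fMin) / object@samplingOct) + 1
  if (length(foi) != expected)
    msg <- c(msg, sprintf("expected %d frequencies, got %d",
                          expected, length(foi)))
  if (length(msg)) msg else TRUE
})

#' Frequency-resolved spectral metrics for one subject
#'
#' @slot psd sensors x freqs power spectral density (units^2/Hz).
#' @slot logPsd log10 of psd.
#' @slot cov freqs x sensors x sensors real covariance of the wavelet
#'   coefficients (diagonal = unscaled power).
#' @slot dwpli debiased squared weighted phase-lag index, NA diagonal.
#' @slot envCorr Pearson correlation of log power envelopes, unit
#'   diagonal.
#' @slot nObs valid sample count per frequency.
#' @slot foi,sensorIds axis labels.
#' @exportClass SpectralTensors
setClass("SpectralTensors",
  representation(
    psd = "matrix", logPsd = "matrix",
    cov = "array", dwpli = "array", envCorr = "array",
    nObs = "numeric", foi = "numeric", sensorIds = "character"
  )
)

#' A set of SPD matrices at one frequency
#'
#' The unit of Riemannian statistics: matrices after common-subspace
#' projection and trace-scaled regularization, guaranteed strictly
#' positive definite.
#'
#' @slot matrices n x rank x rank array.
#' @slot rank subspace dimension.
#' @slot reg regularization scalar (applied as reg * trace/dim * I).
#' @slot filters projection matrix (original dim x rank).
#' @exportClass SPDMatrixSet
setClass("SPDMatrixSet",
  representation(
    matrices = "array", rank = "numeric", reg = "numeric",
    filters = "matrix"
  )
)

setValidity("SPDMatrixSet", function(object) {
  d <- dim(object@matrices)
  if (length(d) != 3 || d[2] != d[3]) return("matrices must be n x r x r")
  if (d[2] != object@rank) return("matrix dimension must equal rank")
  TRUE
})

#' TFCE permutation-test result
#'
#' @slot stat observed statistic map (signed t), vector (freq) or
#'   matrix (sensor x freq).
#' @slot tfce TFCE-enhanced |map| at the observed data.
#' @slot pCorrected per-point corrected p-values (max-statistic null).
#' @slot sigMask logical map at the chosen alpha.
#' @slot E,H,nPerm,alpha TFCE and permutation parameters.
#' @exportClass ClusterTestResult
setClass("ClusterTestResult",
  representation(
    stat = "ANY", tfce = "ANY", pCorrected = "ANY", sigMask = "ANY",
    E = "numeric", H = "numeric", nPerm = "numeric", alpha = "numeric"
  )
)

#' Cross-validated stacking result
#'
#' @slot aucs splits x models matrix of held-out AUCs (marginal models
#'   and the full stack).
#' @slot models model names (column order of aucs).
#' @slot scoreMatrix subjects x blocks cross-fitted score matrix of the
#'   last repeat (second-layer input).
#' @slot foldIds list per repeat of fold assignments.
#' @slot config the stacking configuration used.
#' @slot artifacts per-split second-layer models and fold bookkeeping
#'   (consumed by the conditional permutation importance machinery).
#' @exportClass StackingResult
setClass("StackingResult",
  representation(
    aucs = "matrix", models = "character", scoreMatrix = "matrix",
    foldIds = "list", config = "list", artifacts = "list"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "SensorLayout", function(object) {
  cat("SensorLayout with", length(object@sensorIds), "sensors;",
      sum(object@posteriorMask), "posterior;",
      "mean degree", round(mean(rowSums(object@adjacency)), 2), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nProg, "progressors /", object@nStable,
      "stable over", nrow(object@siteTable), "sites\n")
  cat("  signals:", object@nEpochs, "x", object@epochLenS, "s epochs at",
      object@fs, "Hz on", object@nSensors, "sensors\n")
  cat("  beta power reduction:",
      object@effectSizes$betaPowerReduction, "\n")
})

setMethod("show", "MEGCohort", function(object) {
  tab <- table(object@table$group, object@table$site)
  cat("MEGCohort with", nrow(object@table), "subjects",
      if (length(object@signals)) "(signals attached)" else "(table only)",
      "\n")
  print(tab)
})

setMethod("show", "WaveletFamily", function(object) {
  cat("WaveletFamily:", length(object@foi), "wavelets,",
      object@fMin, "-", object@fMax, "Hz, bandwidth",
      object@bandwidthOct, "oct, step", object@samplingOct, "oct at",
      object@fs, "Hz\n")
})

setMethod("show", "SpectralTensors", function(object) {
  cat("SpectralTensors:", length(object@sensorIds), "sensors x",
      length(object@foi), "frequencies (psd, cov, dwpli, envCorr)\n")
})

setMethod("show", "SPDMatrixSet", function(object) {
  cat("SPDMatrixSet:", dim(object@matrices)[1], "matrices of rank",
      object@rank, "(reg", object@reg, ")\n")
})

setMethod("show", "ClusterTestResult", function(object) {
  cat("ClusterTestResult (E =", object@E, ", H =", object@H, ",",
      object@nPerm, "permutations):", sum(object@sigMask),
      "significant points at alpha", object@alpha, "\n")
})

setMethod("show", "StackingResult", function(object) {
  m <- colMeans(object@aucs, na.rm = TRUE)
  cat("StackingResult over", nrow(object@aucs), "CV splits\n")
  print(round(sort(m, decreasing = TRUE), 3))
})

## ---- accessors ----------------------------------------------------------

#' @rdname MEGCohort-class
#' @param object an object.
#' @export
setGeneric("cohortTable", function(object) standardGeneric("cohortTable"))

#' @rdname MEGCohort-class
setMethod("cohortTable", "MEGCohort", function(object) object@table)

#' @rdname MEGCohort-class
#' @param id subject identifier.
#' @export
setGeneric("subjectSignals",
           function(object, id) standardGeneric("subjectSignals"))

#' @rdname MEGCohort-class
setMethod("subjectSignals", "MEGCohort",
          function(object, id) object@signals[[id]])

#' @rdname SensorLayout-class
#' @param object an object.
#' @export
setGeneric("posteriorMask", function(object) standardGeneric("posteriorMask"))

#' @rdname SensorLayout-class
setMethod("posteriorMask", "SensorLayout",
          function(object) object@posteriorMask)

#' @rdname SensorLayout-class
#' @export
setGeneric("sensorAdjacency",
           function(object) standardGeneric("sensorAdjacency"))

#' @rdname SensorLayout-class
setMethod("sensorAdjacency", "SensorLayout", function(object) object@adjacency)

#' @rdname WaveletFamily-class
#' @param object an object.
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname WaveletFamily-class
setMethod("frequencies", "WaveletFamily", function(object) object@foi)

#' @rdname SpectralTensors-class
setMethod("frequencies", "SpectralTensors", function(object) object@foi)

#' @rdname SPDMatrixSet-class
#' @param object an object.
#' @export
setGeneric("spdMatrices", function(object) standardGeneric("spdMatrices"))

#' @rdname SPDMatrixSet-class
setMethod("spdMatrices", "SPDMatrixSet", function(object) object@matrices)
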