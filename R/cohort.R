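#' Construct a cohort specification
#'
#' Defaults encode the study conditions the pipeline targets: 64
#' progressors and 53 stable MCI patients split over two sites (CTB
#' 41/49, CBU 23/4), group-wise demographic distributions, an MRI block
#' with a planted hippocampal-ratio deficit in progressors, 2 min of
#' signal per subject (12 x 10 s epochs at 250 Hz) on 102 sensors, and
#' the missingness pattern 15 education / 5 MMSE / 13 whole MRI blocks.
#'
#' Planted signal effects (all switchable to 0 for null cohorts):
#' `betaPowerReduction` multiplies the 16-38 Hz posterior source
#' amplitude by `1 - value` in progressors; `lowfreqCovShift` correlates
#' the two delta-theta sources in progressors with per-sensor power
#' matched, so only the sensor covariance differs; `alphaPlvShift`
#' weakens the 90-degree phase-lagged ~9 Hz coupling; `envCorrShift`
#' weakens the shared slow amplitude modulation of a 13-17 Hz source
#' pair.
#'
#' @param nProg,nStable group sizes.
#' @param siteTable 2 x 2 matrix (rows CTB, CBU; cols progression,
#'   stable).
#' @param effectSizes,demographics,mriParams,missingCounts optional
#'   overrides merged into the defaults.
#' @param nEpochs,epochLenS,fs,nSensors signal geometry.
#' @param seed master seed; the cohort is a pure function of the spec.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nProg = 64, nStable = 53,
                       siteTable = NULL,
                       effectSizes = list(), demographics = list(),
                       mriParams = list(), missingCounts = list(),
                       nEpochs = 12, epochLenS = 10, fs = 250,
                       nSensors = 102, seed = 1) {
  if (is.null(siteTable)) {
    if (nProg == 64 && nStable == 53) {
      siteTable <- matrix(c(41, 23, 49, 4), 2, 2,
                          dimnames = list(c("CTB", "CBU"),
                                          c("progression", "stable")))
    } else {
      # proportional split, CTB-heavy, preserving totals
      p1 <- round(nProg * 41 / 64); s1 <- round(nStable * 49 / 53)
      siteTable <- matrix(c(p1, nProg - p1, s1, nStable - s1), 2, 2,
                          dimnames = list(c("CTB", "CBU"),
                                          c("progression", "stable")))
    }
  }
  es <- utils::modifyList(list(
    betaPowerReduction = 0.3, lowfreqCovShift = 0.5,
    alphaPlvShift = 0.3, envCorrShift = 0.3), effectSizes)
  dg <- utils::modifyList(list(
    progression = list(age = c(73.03, 6.98), education = c(10.24, 4.54),
                       mmse = c(25.54, 2.82), mmseRange = c(17, 30),
                       maleProp = 32 / 64),
    stable = list(age = c(72.47, 5.32), education = c(8.58, 4.50),
                  mmse = c(27.15, 2.41), mmseRange = c(22, 30),
                  maleProp = 20 / 53)), demographics)
  mri <- utils::modifyList(list(
    hippRatio = list(progression = c(0.0050, 7e-4),
                     stable = c(0.0055, 7e-4)),
    totalGrey = c(6e5, 5e4),
    regional = c(8000, 1500), regionalAtrophy = 0.06,
    nRegions = 64), mriParams)
  mc <- utils::modifyList(list(education = 15, mmse = 5, mri = 13),
                          missingCounts)
  new("CohortSpec", nProg = nProg, nStable = nStable,
      siteTable = siteTable, demographics = dg, mriParams = mri,
      effectSizes = es, missingCounts = mc, nEpochs = nEpochs,
      epochLenS = epochLenS, fs = fs, nSensors = nSensors, seed = seed)
}

## ---- signal primitives --------------------------------------------------

#' 1/f-shaped broadband noise, one column per sensor
#'
#' White noise spectrally shaped with amplitude 1/sqrt(f) (power
#' exponent 1), floored at 1 Hz to keep DC finite; unit variance per
#' column in expectation.
#' @noRd
oneOverFNoise <- function(n, p, fs) {
  w <- matrix(rnorm(n * p), n, p)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- 1 / sqrt(pmax(f, 1))
  g[1] <- 0 # remove DC
  X <- Re(mvfft(mvfft(w) * g, inverse = TRUE)) / n
  X / sqrt(mean(g^2))
}

#' Band-limited source: 4th-order Butterworth band-pass of white noise
#' @noRd
bandSource <- function(n, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  # pad to suppress filtfilt edge transients on short epochs
  pad <- min(n, 4 * ceiling(fs / band[1]))
  x <- signal::filtfilt(bf, rnorm(n + 2 * pad))
  x <- x[(pad + 1):(pad + n)]
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("band-pass source degenerate")
  x / s
}

#' 90-degree phase-shifted copy via the analytic signal
#' @noRd
hilbertShift <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Im(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Cohort-level source topographies
#'
#' Deterministic given the spec seed and layout: the same smooth mixing
#' fields are shared by every subject of a cohort (subjects add a small
#' jitter), so planted covariance/coupling effects have a consistent
#' sensor-space direction across the cohort.
#' @noRd
cohortMixing <- function(spec, layout) {
  withLocalSeed(spec@seed * 31 + 17, {
    postW <- ifelse(layout@posteriorMask, 1, 0.1)
    postField <- function() {
      f <- abs(smoothField(layout@positions)) * postW
      f / sqrt(sum(f^2))
    }
    list(mAlpha = postField(), mBeta = postField(),
         u = smoothField(layout@positions),
         v = smoothField(layout@positions),
         p1 = smoothField(layout@positions),
         p2 = smoothField(layout@positions),
         q1 = smoothField(layout@positions),
         q2 = smoothField(layout@positions))
  })
}

## ---- subject simulation -------------------------------------------------

#' Simulate one subject
#'
#' Signals are a mixed sum of a 1/f background, a posterior ~10 Hz alpha
#' source, a posterior 16-38 Hz source (amplitude reduced by
#' `betaPowerReduction` in progressors), a delta-theta source pair whose
#' sensor covariance (but not per-sensor power) differs between groups,
#' a ~9 Hz source pair with a 90-degree phase lag, and a 13-17 Hz source
#' pair with correlated slow amplitude envelopes. Demographics and MRI
#' are drawn from group-specific Gaussians; MMSE is clipped to the
#' group's observed range. With all effect sizes zero, the group label
#' does not enter signal generation.
#'
#' @param spec a [CohortSpec-class].
#' @param layout a [SensorLayout-class].
#' @param group `"progression"` or `"stable"`.
#' @param site `"CTB"` or `"CBU"`.
#' @param seed integer substream seed for this subject.
#' @return list with `covariates` (one-row data.frame) and `signals`
#'   (epochs x sensors x samples array).
#' @export
simulateSubject <- function(spec, layout, group, site, seed) {
  if (!group %in% c("progression", "stable"))
    stop("unknown group label: ", group)
  if (!site %in% rownames(spec@siteTable))
    stop("unknown site label: ", site)
  withLocalSeed(seed, {
    p <- length(layout@sensorIds)
    n <- round(spec@fs * spec@epochLenS)
    fs <- spec@fs
    es <- spec@effectSizes
    prog <- group == "progression"

    # mixing vectors: cohort-level smooth fields (same source
    # topographies for every subject, as shared anatomy implies) plus a
    # small per-subject jitter
    cm <- cohortMixing(spec, layout)
    jitter <- function(m0, posteriorWeighted = FALSE) {
      f <- smoothField(layout@positions)
      if (posteriorWeighted) {
        postW <- ifelse(layout@posteriorMask, 1, 0.1)
        f <- abs(f) * postW
        f <- f / sqrt(sum(f^2))
      }
      m <- m0 + 0.4 * f
      m / sqrt(sum(m^2))
    }
    mAlpha <- jitter(cm$mAlpha, TRUE)
    mBeta <- jitter(cm$mBeta, TRUE)
    u <- jitter(cm$u)
    v <- jitter(cm$v)
    p1 <- jitter(cm$p1)
    p2 <- jitter(cm$p2)
    q1 <- jitter(cm$q1)
    q2 <- jitter(cm$q2)

    # per-subject amplitude variability (lognormal), the dominant
    # between-subject factor in resting M/EEG power
    gGlobal <- exp(rnorm(1, 0, 0.1))
    gSrc <- exp(rnorm(5, 0, 0.25))
    aAlpha <- 1.5 * gSrc[1]
    aBeta <- 2.0 * gSrc[2] *
      (1 - if (prog) es$betaPowerReduction else 0)
    aLow <- 1.0 * gSrc[3]
    aPlv <- 0.6 * gSrc[4]
    aEnv <- 0.6 * gSrc[5]

    # delta-theta covariance effect: correlate the sources in
    # progressors, then rescale each sensor's low-frequency mixing so
    # per-sensor power is matched between groups
    rho <- if (prog) es$lowfreqCovShift else 0
    diag0 <- u^2 + v^2
    diagR <- u^2 + v^2 + 2 * rho * u * v
    lowScale <- sqrt(diag0 / pmax(diagR, 1e-12))

    kPlv <- 0.6 * (1 - if (prog) es$alphaPlvShift else 0)
    kEnv <- 0.7 * (1 - if (prog) es$envCorrShift else 0)

    sig <- array(0, dim = c(spec@nEpochs, p, n))
    for (e in seq_len(spec@nEpochs)) {
      X <- oneOverFNoise(n, p, fs)

      sAlpha <- bandSource(n, c(8, 12), fs)
      X <- X + aAlpha * outer(sAlpha, mAlpha)

      sBeta <- bandSource(n, c(16, 38), fs)
      X <- X + aBeta * outer(sBeta, mBeta)

      s1 <- bandSource(n, c(2, 6), fs)
      s2 <- bandSource(n, c(2, 6), fs)
      s2r <- rho * s1 + sqrt(1 - rho^2) * s2
      L <- outer(s1, u * lowScale) + outer(s2r, v * lowScale)
      X <- X + aLow * L

      sP <- bandSource(n, c(8.5, 9.5), fs)
      sPh <- hilbertShift(sP)
      sInd <- bandSource(n, c(8.5, 9.5), fs)
      X <- X + aPlv * (outer(sP, p1) +
                       outer(kPlv * sPh + sqrt(1 - kPlv^2) * sInd, p2))

      mSlow <- bandSource(n, c(0.2, 1), fs)
      m2 <- bandSource(n, c(0.2, 1), fs)
      env1 <- 1 + 0.5 * tanh(mSlow)
      env2 <- 1 + 0.5 * tanh(kEnv * mSlow + sqrt(1 - kEnv^2) * m2)
      c1 <- bandSource(n, c(13, 17), fs)
      c2 <- bandSource(n, c(13, 17), fs)
      X <- X + aEnv * (outer(env1 * c1, q1) + outer(env2 * c2, q2))

      sig[e, , ] <- gGlobal * t(X)
    }
    stopifnot(all(is.finite(sig)))

    dgp <- spec@demographics[[group]]
    mmse <- rnorm(1, dgp$mmse[1], dgp$mmse[2])
    mmse <- min(max(mmse, dgp$mmseRange[1]), dgp$mmseRange[2])
    hr <- spec@mriParams$hippRatio[[group]]
    ratio <- max(rnorm(1, hr[1], hr[2]), 1e-4)
    tgm <- max(rnorm(1, spec@mriParams$totalGrey[1],
                     spec@mriParams$totalGrey[2]), 1e5)
    nReg <- spec@mriParams$nRegions
    atro <- if (prog) 1 - spec@mriParams$regionalAtrophy else 1
    vols <- c(ratio * tgm,
              rnorm(nReg - 1, atro * spec@mriParams$regional[1],
                    spec@mriParams$regional[2]))
    cov1 <- data.frame(
      group = group, site = site,
      sex = if (rbinom(1, 1, dgp$maleProp) == 1) "M" else "F",
      age = rnorm(1, dgp$age[1], dgp$age[2]),
      education = max(rnorm(1, dgp$education[1], dgp$education[2]), 0),
      mmse = mmse,
      hippocampal_ratio = ratio, total_grey_matter = tgm,
      stringsAsFactors = FALSE)
    volDf <- as.data.frame(as.list(vols))
    names(volDf) <- sprintf("vol_%d", seq_len(nReg))
    list(covariates = cbind(cov1, volDf), signals = sig)
  })
}

#' Simulate a full cohort
#'
#' Subjects are generated per site x group cell of `spec@siteTable`,
#' each from a deterministic substream of the master seed, so the
#' cohort is a pure function of the spec.
#'
#' @param spec a [CohortSpec-class].
#' @param layout optional [SensorLayout-class]; built from the spec if
#'   missing.
#' @param signals if `FALSE`, only the covariate table is generated
#'   (signals list left empty) - useful when only demographics matter.
#' @return a [MEGCohort-class].
#' @export
#' @examples
#' spec <- cohortSpec(nProg = 3, nStable = 2, nSensors = 8,
#'                    nEpochs = 1, epochLenS = 2, fs = 64, seed = 1)
#' coh <- simulateCohort(spec)
#' table(cohortTable(coh)$group)
simulateCohort <- function(spec, layout = NULL, signals = TRUE) {
  validObject(spec)
  if (is.null(layout)) layout <- makeLayout(spec@nSensors, seed = spec@seed)
  rows <- list(); sigList <- list()
  idx <- 0
  for (site in rownames(spec@siteTable)) {
    for (group in colnames(spec@siteTable)) {
      for (k in seq_len(spec@siteTable[site, group])) {
        idx <- idx + 1
        subSeed <- (spec@seed * 10007 + idx * 7919) %% 2147483647
        if (signals) {
          s <- simulateSubject(spec, layout, group, site, subSeed)
        } else {
          s <- withLocalSeed(subSeed + 1, {
            # reuse the covariate path only (signal draws skipped)
            simulateCovariatesOnly(spec, group, site)
          })
        }
        id <- sprintf("sub-%03d", idx)
        s$covariates <- cbind(data.frame(subject_id = id,
                                         stringsAsFactors = FALSE),
                              s$covariates)
        rows[[idx]] <- s$covariates
        if (signals) sigList[[id]] <- s$signals
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("MEGCohort", table = tab, signals = sigList, layout = layout,
      spec = spec)
}

#' @noRd
simulateCovariatesOnly <- function(spec, group, site) {
  dgp <- spec@demographics[[group]]
  mmse <- rnorm(1, dgp$mmse[1], dgp$mmse[2])
  mmse <- min(max(mmse, dgp$mmseRange[1]), dgp$mmseRange[2])
  hr <- spec@mriParams$hippRatio[[group]]
  ratio <- max(rnorm(1, hr[1], hr[2]), 1e-4)
  tgm <- max(rnorm(1, spec@mriParams$totalGrey[1],
                   spec@mriParams$totalGrey[2]), 1e5)
  nReg <- spec@mriParams$nRegions
  atro <- if (group == "progression")
    1 - spec@mriParams$regionalAtrophy else 1
  vols <- c(ratio * tgm, rnorm(nReg - 1,
                               atro * spec@mriParams$regional[1],
                               spec@mriParams$regional[2]))
  cov1 <- data.frame(
    group = group, site = site,
    sex = if (rbinom(1, 1, dgp$maleProp) == 1) "M" else "F",
    age = rnorm(1, dgp$age[1], dgp$age[2]),
    education = max(rnorm(1, dgp$education[1], dgp$education[2]), 0),
    mmse = mmse, hippocampal_ratio = ratio, total_grey_matter = tgm,
    stringsAsFactors = FALSE)
  volDf <- as.data.frame(as.list(vols))
  names(volDf) <- sprintf("vol_%d", seq_len(nReg))
  list(covariates = cbind(cov1, volDf))
}

#' Inject the study's missingness pattern
#'
#' Sets exactly `missingCounts$education` education values,
#' `missingCounts$mmse` MMSE values and `missingCounts$mri` whole MRI
#' blocks (ratio, total grey matter and all regional volumes) to `NA`,
#' chosen uniformly at random from a seeded stream. Group labels are
#' never touched.
#'
#' @param cohort a [MEGCohort-class].
#' @param spec optional [CohortSpec-class]; defaults to the cohort's.
#' @return the modified cohort.
#' @export
injectMissingness <- function(cohort, spec = cohort@spec) {
  mc <- spec@missingCounts
  n <- nrow(cohort@table)
  if (any(unlist(mc) > n))
    stop("requested missingness count exceeds cohort size")
  withLocalSeed(spec@seed + 104729, {
    tab <- cohort@table
    if (mc$education > 0)
      tab$education[sample.int(n, mc$education)] <- NA
    if (mc$mmse > 0)
      tab$mmse[sample.int(n, mc$mmse)] <- NA
    if (mc$mri > 0) {
      mriCols <- c("hippocampal_ratio", "total_grey_matter",
                   grep("^vol_", names(tab), value = TRUE))
      tab[sample.int(n, mc$mri), mriCols] <- NA
    }
    cohort@table <- tab
    cohort
  })
}
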