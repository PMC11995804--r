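#' Build a family of log2-spaced Morlet wavelets
#'
#' Centre frequencies run from `fMin` to `fMax` in steps of
#' `samplingOct` octaves (121 wavelets for 1-64 Hz at 0.05). Each
#' kernel is a complex exponential under a Gaussian envelope whose
#' spectral half-power edges sit at `f * 2^(+-bandwidthOct/2)`:
#' `sigma_f = f (2^(b/2) - 2^(-b/2)) / (2 sqrt(2 ln 2))`,
#' `sigma_t = 1 / (2 pi sigma_f)`. Kernels are truncated at
#' `+-5 sigma_t` and normalized to unit spectral peak gain; the
#' truncation halfwidth doubles as the edge-invalidation halfwidth.
#'
#' @param fMin,fMax frequency range in Hz (`fMax <= fs/2`).
#' @param bandwidthOct spectral smoothing in octaves (default 0.35).
#' @param samplingOct grid step in octaves (default 0.05).
#' @param fs sampling rate in Hz.
#' @return a [WaveletFamily-class].
#' @export
#' @examples
#' fam <- buildWaveletFamily(1, 64, 0.35, 0.05, 250)
#' length(frequencies(fam)) # 121
buildWaveletFamily <- function(fMin = 1, fMax = 64, bandwidthOct = 0.35,
                               samplingOct = 0.05, fs = 250) {
  if (fMin <= 0 || fMax <= fMin) stop("need 0 < fMin < fMax")
  if (fMax > fs / 2) stop("fMax above Nyquist (fs/2): aliasing")
  if (bandwidthOct <= 0 || samplingOct <= 0)
    stop("bandwidthOct and samplingOct must be > 0")
  k <- round(log2(fMax / fMin) / samplingOct)
  foi <- fMin * 2^(seq(0, k) * samplingOct)
  b <- bandwidthOct
  kernels <- vector("list", length(foi))
  hw <- integer(length(foi))
  neb <- numeric(length(foi))
  for (i in seq_along(foi)) {
    f <- foi[i]
    # half-power convention: |H(f 2^(+-b/2))|^2 = 1/2 of peak
    sigmaF <- f * (2^(b / 2) - 2^(-b / 2)) / (2 * sqrt(log(2)))
    sigmaT <- 1 / (2 * pi * sigmaF)
    hw[i] <- as.integer(ceiling(5 * sigmaT * fs))
    t <- seq(-hw[i], hw[i]) / fs
    env <- exp(-t^2 / (2 * sigmaT^2))
    w <- exp(2i * pi * f * t) * env
    w <- w / sum(env) # unit gain at the centre frequency
    kernels[[i]] <- w
    # noise-equivalent bandwidth from a finely resolved transfer function
    N <- nextn(max(32 * length(w), 4096))
    H2 <- Mod(fft(c(w, rep(0, N - length(w)))))^2
    neb[i] <- sum(H2) * (fs / N) / max(H2)
  }
  new("WaveletFamily", foi = foi, fMin = fMin, fMax = fMax,
      bandwidthOct = bandwidthOct, samplingOct = samplingOct, fs = fs,
      kernels = kernels, validHalfwidth = hw, neb = neb)
}

#' Wavelet-convolve epoched signals
#'
#' FFT-based convolution of every epoch and sensor with every kernel.
#' Samples within the kernel truncation halfwidth of either epoch edge
#' are invalid and excluded; valid samples are pooled over epochs.
#' Frequencies whose halfwidth leaves no valid samples are flagged
#' unusable and dropped from the output (with a warning); an error is
#' raised if no frequency survives.
#'
#' @param signals epochs x sensors x samples array.
#' @param family a [WaveletFamily-class].
#' @return list with `coeffs` (per usable frequency, a pooled
#'   valid-samples x sensors complex matrix), `nObs`, `foi`, `usable`
#'   (logical over the family grid), `neb`.
#' @export
convolveEpochs <- function(signals, family) {
  d <- dim(signals)
  if (length(d) != 3) stop("signals must be epochs x sensors x samples")
  nEp <- d[1]; p <- d[2]; n <- d[3]
  usable <- 2L * family@validHalfwidth < n
  if (!any(usable))
    stop("epoch too short: no usable frequency in the family")
  if (!all(usable))
    warning(sum(!usable), " frequencies unusable at epoch length ", n)
  idx <- which(usable)
  coeffs <- vector("list", length(idx))
  names(coeffs) <- as.character(family@foi[idx])
  for (j in seq_along(idx)) {
    i <- idx[j]
    ker <- family@kernels[[i]]
    hw <- family@validHalfwidth[i]
    len <- length(ker)
    N <- nextn(n + len - 1)
    Fk <- fft(c(ker, rep(0, N - len)))
    valid <- (hw + 1):(n - hw)
    out <- matrix(0i, length(valid) * nEp, p)
    for (e in seq_len(nEp)) {
      X <- t(signals[e, , , drop = TRUE])
      if (p == 1) X <- matrix(signals[e, 1, ], ncol = 1)
      Xp <- rbind(X, matrix(0, N - n, p))
      Y <- mvfft(mvfft(Xp) * Fk, inverse = TRUE) / N
      seg <- Y[(hw + 1):(hw + n), , drop = FALSE] # "same" alignment
      out[((e - 1) * length(valid) + 1):(e * length(valid)), ] <-
        seg[valid, , drop = FALSE]
    }
    coeffs[[j]] <- out
  }
  list(coeffs = coeffs, nObs = vapply(coeffs, nrow, 1L),
       foi = family@foi[idx], usable = usable, neb = family@neb[idx])
}

#' Power spectral density from wavelet coefficients
#'
#' `psd(sensor, f)` is the mean over valid samples of `|c|^2`, scaled
#' to one-sided density units^2/Hz by `2 / NEB(f)` where NEB is the
#' kernel's noise-equivalent bandwidth; epochs are pooled before the
#' log10 is taken.
#'
#' @param conv output of [convolveEpochs()].
#' @return list with `psd` and `logPsd` (sensors x freqs) and `foi`.
#' @export
computePower <- function(conv) {
  p <- ncol(conv$coeffs[[1]])
  psd <- matrix(NA_real_, p, length(conv$foi))
  for (j in seq_along(conv$coeffs)) {
    X <- conv$coeffs[[j]]
    if (nrow(X) < 1) next # reported missing, not zero
    psd[, j] <- 2 * colMeans(Mod(X)^2) / conv$neb[j]
  }
  colnames(psd) <- as.character(conv$foi)
  list(psd = psd, logPsd = log10(psd), foi = conv$foi)
}

#' Sensor covariance of wavelet coefficients, per frequency
#'
#' Real part of the averaged outer product over valid samples; the
#' diagonal equals the unscaled mean power.
#'
#' @param conv output of [convolveEpochs()].
#' @return freqs x sensors x sensors array.
#' @export
computeCovariance <- function(conv) {
  p <- ncol(conv$coeffs[[1]])
  out <- array(NA_real_, c(length(conv$foi), p, p))
  for (j in seq_along(conv$coeffs)) {
    X <- conv$coeffs[[j]]
    if (nrow(X) < 2) stop("fewer than 2 valid samples at ",
                          conv$foi[j], " Hz")
    C <- Re(crossprod(Conj(X), X)) / nrow(X)
    out[j, , ] <- (C + t(C)) / 2
  }
  out
}

#' Debiased squared weighted phase-lag index, per frequency
#'
#' With `I_j = Im(X_j conj(Y_j))` over valid samples:
#' `dwpli = (sum(I)^2 - sum(I^2)) / (sum(|I|)^2 - sum(I^2))`.
#' Pairs with a zero denominator (e.g. identical signals with no
#' imaginary cross-spectrum) are reported missing; the diagonal is NA.
#'
#' @param conv output of [convolveEpochs()].
#' @return freqs x sensors x sensors array in (-Inf, 1].
#' @export
computeDwpli <- function(conv) {
  p <- ncol(conv$coeffs[[1]])
  out <- array(NA_real_, c(length(conv$foi), p, p))
  for (j in seq_along(conv$coeffs)) {
    X <- conv$coeffs[[j]]
    if (nrow(X) < 2) stop("fewer than 2 valid samples at ",
                          conv$foi[j], " Hz")
    acc <- dwpli_accumulate_cpp(X)
    num <- acc$sumI^2 - acc$sumI2
    den <- acc$sumAbsI^2 - acc$sumI2
    v <- num / den
    v[den <= .Machine$double.eps * acc$sumI2] <- NA
    diag(v) <- NA
    out[j, , ] <- v
  }
  out
}

#' Power-envelope correlation, per frequency
#'
#' The power envelope is `log(|c| + eps)` with
#' `eps = 1e-12 * median(|c|)` as a numerical guard; envelopes are
#' correlated (Pearson) across valid samples pooled over epochs.
#' Constant envelopes give missing values; the diagonal is 1.
#'
#' @param conv output of [convolveEpochs()].
#' @return freqs x sensors x sensors array in [-1, 1].
#' @export
computeEnvCorr <- function(conv) {
  p <- ncol(conv$coeffs[[1]])
  out <- array(NA_real_, c(length(conv$foi), p, p))
  for (j in seq_along(conv$coeffs)) {
    X <- conv$coeffs[[j]]
    if (nrow(X) < 3) stop("fewer than 3 valid samples at ",
                          conv$foi[j], " Hz")
    A <- Mod(X)
    eps <- 1e-12 * stats::median(A)
    E <- log(A + eps)
    sds <- apply(E, 2, sd)
    C <- suppressWarnings(cor(E))
    C[sds == 0, ] <- NA
    C[, sds == 0] <- NA
    diag(C) <- 1
    out[j, , ] <- C
  }
  out
}

#' All four spectral metrics for one subject
#'
#' @param signals epochs x sensors x samples array.
#' @param family a [WaveletFamily-class].
#' @param sensorIds optional sensor labels.
#' @param metrics subset of `c("psd", "cov", "dwpli", "envCorr")`.
#' @return a [SpectralTensors-class] (unrequested metrics are empty).
#' @export
spectralFeatures <- function(signals, family, sensorIds = NULL,
                             metrics = c("psd", "cov", "dwpli",
                                         "envCorr")) {
  conv <- convolveEpochs(signals, family)
  p <- ncol(conv$coeffs[[1]])
  if (is.null(sensorIds)) sensorIds <- sprintf("MEG%03d", seq_len(p))
  empty <- array(numeric(0), c(0, p, p))
  pw <- if ("psd" %in% metrics) computePower(conv) else
    list(psd = matrix(numeric(0), p, 0),
         logPsd = matrix(numeric(0), p, 0))
  new("SpectralTensors",
      psd = pw$psd, logPsd = pw$logPsd,
      cov = if ("cov" %in% metrics) computeCovariance(conv) else empty,
      dwpli = if ("dwpli" %in% metrics) computeDwpli(conv) else empty,
      envCorr = if ("envCorr" %in% metrics) computeEnvCorr(conv) else
        empty,
      nObs = as.numeric(conv$nObs), foi = conv$foi,
      sensorIds = sensorIds)
}

#' Node strength of a symmetric matrix metric
#'
#' Per sensor, the mean of the off-diagonal entries in its row (missing
#' entries excluded) - the mean-degree summary used to reduce
#' connectivity matrices to one value per sensor. For a freqs x
#' sensors x sensors array, returns sensors x freqs.
#'
#' @param x symmetric matrix or freqs x sensors x sensors array.
#' @return numeric vector (matrix input) or sensors x freqs matrix.
#' @export
nodeStrength <- function(x) {
  strength1 <- function(m) {
    diag(m) <- NA
    rowMeans(m, na.rm = TRUE)
  }
  if (is.matrix(x)) return(strength1(x))
  if (length(dim(x)) == 3)
    return(vapply(seq_len(dim(x)[1]), function(f) strength1(x[f, , ]),
                  numeric(dim(x)[2])))
  stop("x must be a matrix or a freqs x sensors x sensors array")
}

#' Integrate a power spectral density over Hz (trapezoid rule)
#'
#' @param psd sensors x freqs matrix (or vector) of densities.
#' @param foi centre frequencies in Hz.
#' @return per-sensor integrated power (units^2).
#' @export
integratePower <- function(psd, foi) {
  if (is.vector(psd)) psd <- matrix(psd, nrow = 1)
  df <- diff(foi)
  mids <- (psd[, -1, drop = FALSE] + psd[, -ncol(psd), drop = FALSE]) / 2
  drop(mids %*% df)
}
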