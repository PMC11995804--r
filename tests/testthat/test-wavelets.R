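test_that("the frequency grid matches the octave arithmetic", {
  fam <- buildWaveletFamily(1, 64, 0.35, 0.05, 250)
  expect_length(frequencies(fam), 121)
  expect_length(frequencies(buildWaveletFamily(1, 64, 0.35, 0.25, 250)),
                25)
  # count = span/step + 1 for exact divisions of the 6-octave span
  for (s in c(0.1, 0.2, 0.5)) {
    fam2 <- buildWaveletFamily(1, 64, 0.35, s, 250)
    expect_length(frequencies(fam2), round(6 / s) + 1)
    expect_equal(diff(log2(frequencies(fam2))),
                 rep(s, round(6 / s)), tolerance = 1e-9)
  }
  expect_error(buildWaveletFamily(1, 130, 0.35, 0.05, 250), "aliasing")
  expect_error(buildWaveletFamily(0, 64, 0.35, 0.05, 250))
})

test_that("kernels carry half-power edges at f 2^(+-b/2)", {
  fam <- buildWaveletFamily(1, 64, 0.35, 0.05, 250)
  i <- which.min(abs(frequencies(fam) - 10))
  f0 <- frequencies(fam)[i]
  ker <- fam@kernels[[i]]
  N <- nextn(64 * length(ker))
  H <- Mod(fft(c(ker, rep(0, N - length(ker)))))
  fr <- (0:(N - 1)) * 250 / N
  gain <- function(f) approx(fr[1:(N / 2)], H[1:(N / 2)], f)$y / max(H)
  up <- gain(f0 * 2^(0.35 / 2))
  lo <- gain(f0 * 2^(-0.35 / 2))
  # the Gaussian is symmetric in linear frequency while octave edges
  # are not: each edge sits near 1/sqrt(2), their geometric mean on it
  expect_lt(abs(up - 1 / sqrt(2)), 0.05)
  expect_lt(abs(lo - 1 / sqrt(2)), 0.05)
  expect_lt(abs(sqrt(up * lo) - 1 / sqrt(2)), 0.01)
})

test_that("convolution is frequency selective and flags epoch edges", {
  fs <- 250
  fam <- buildWaveletFamily(4, 32, 0.35, 0.25, fs)
  t <- (0:(4 * fs - 1)) / fs
  f0 <- 8 # on the grid: 4 * 2^1
  sig <- array(cos(2 * pi * f0 * t), c(1, 1, length(t)))
  conv <- convolveEpochs(sig, fam)
  amp <- vapply(conv$coeffs, function(X) mean(Mod(X)), 1.0)
  expect_equal(unname(which.max(amp)), which.min(abs(conv$foi - f0)))

  zero <- array(0, c(1, 2, 500))
  famz <- buildWaveletFamily(8, 32, 0.35, 0.5, fs)
  cz <- convolveEpochs(zero, famz)
  expect_true(all(vapply(cz$coeffs, function(X) all(Mod(X) == 0), TRUE)))

  # validity mask drops exactly the truncation halfwidth at both ends;
  # the 1 Hz kernel outgrows the epoch and is flagged unusable
  n <- 10 * fs
  sig2 <- array(rnorm(2 * n), c(2, 1, n))
  fam1 <- buildWaveletFamily(1, 4, 0.35, 1, fs)
  expect_warning(c1 <- convolveEpochs(sig2, fam1), "unusable")
  iu <- which(c1$usable)
  expect_false(c1$usable[1])
  hw <- fam1@validHalfwidth[iu[1]]
  expect_equal(unname(c1$nObs[1]), 2 * (n - 2 * hw))

  # epochs too short for every frequency -> error
  expect_error(convolveEpochs(array(rnorm(40), c(1, 1, 40)), fam1),
               "no usable frequency")
})

test_that("power is densitometric: flat for white noise, Parseval for tones", {
  fs <- 250
  fam <- buildWaveletFamily(4, 32, 0.35, 0.25, fs)
  set.seed(1)
  sig <- array(rnorm(4 * 2 * 10 * fs), c(4, 2, 10 * fs))
  pw <- computePower(convolveEpochs(sig, fam))
  expect_lt(max(abs(colMeans(pw$psd) - 2 / fs)) / (2 / fs), 0.15)

  a <- 2
  t <- (0:(10 * fs - 1)) / fs
  tone <- array(rep(a * cos(2 * pi * 8 * t), 2), c(1, 2, 10 * fs))
  pwT <- computePower(convolveEpochs(tone, fam))
  expect_equal(unname(integratePower(pwT$psd[1, ], pwT$foi)), a^2 / 2,
               tolerance = 0.1)

  # quadratic amplitude scaling, exactly
  pw2 <- computePower(convolveEpochs(2 * tone, fam))
  expect_equal(pw2$psd, 4 * pwT$psd, tolerance = 1e-12)
})

test_that("covariance is a Gram object and transforms under mixing", {
  fs <- 250
  fam <- buildWaveletFamily(8, 32, 0.35, 0.5, fs)
  set.seed(2)
  n <- 4 * fs
  base <- matrix(rnorm(n * 3), n, 3)
  sig <- array(0, c(1, 3, n))
  sig[1, , ] <- t(base)
  conv <- convolveEpochs(sig, fam)
  cv <- computeCovariance(conv)
  pw <- computePower(conv)
  for (f in seq_along(conv$foi)) {
    M <- cv[f, , ]
    expect_equal(M, t(M))
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * sum(diag(M)))
    # diagonal equals unscaled mean power
    expect_equal(diag(M), unname(pw$psd[, f] * conv$neb[f] / 2),
                 tolerance = 1e-10)
  }
  # identical sensors: off-diagonal equals diagonal
  sig2 <- array(0, c(1, 2, n))
  sig2[1, 1, ] <- base[, 1]; sig2[1, 2, ] <- base[, 1]
  cv2 <- computeCovariance(convolveEpochs(sig2, fam))
  expect_equal(cv2[1, 1, 2], cv2[1, 1, 1], tolerance = 1e-12)
  # linearity: cov(Wx) = W cov(x) W^T (convolution is linear)
  W <- matrix(rnorm(9), 3)
  sigW <- sig
  sigW[1, , ] <- W %*% sig[1, , ]
  cvW <- computeCovariance(convolveEpochs(sigW, fam))
  for (f in seq_along(conv$foi))
    expect_equal(cvW[f, , ], W %*% cv[f, , ] %*% t(W), tolerance = 1e-8)
})

test_that("dwPLI saturates under a fixed lag and nulls out under independence", {
  fs <- 250
  n <- 8 * fs
  t <- (0:(n - 1)) / fs
  fam <- buildWaveletFamily(6, 12, 0.35, 0.5, fs)
  i9 <- which.min(abs(buildWaveletFamily(6, 12, 0.35, 0.5, fs)@foi - 9))
  lag <- array(0, c(1, 2, n))
  lag[1, 1, ] <- sin(2 * pi * 9 * t)
  lag[1, 2, ] <- cos(2 * pi * 9 * t) # constant 90 degree lag
  dw <- computeDwpli(convolveEpochs(lag, fam))
  expect_equal(dw[i9, 1, 2], 1, tolerance = 1e-6)

  set.seed(3)
  ind <- array(rnorm(2 * n), c(1, 2, n))
  dwI <- computeDwpli(convolveEpochs(ind, fam))
  expect_lt(abs(dwI[i9, 1, 2]), 0.05)
  expect_true(all(dwI <= 1, na.rm = TRUE))
  expect_equal(dwI[i9, 1, 2], dwI[i9, 2, 1])

  # identical signals: zero imaginary cross-spectrum -> missing
  same <- array(0, c(1, 2, n))
  same[1, 1, ] <- rnorm(n); same[1, 2, ] <- same[1, 1, ]
  dwS <- computeDwpli(convolveEpochs(same, fam))
  expect_true(is.na(dwS[i9, 1, 2]))

  # invariant to per-sensor amplitude rescaling
  sc <- ind
  sc[1, 2, ] <- 7 * sc[1, 2, ]
  dwSc <- computeDwpli(convolveEpochs(sc, fam))
  expect_equal(dwSc[i9, 1, 2], dwI[i9, 1, 2], tolerance = 1e-10)
})

test_that("envelope correlation tracks shared slow amplitude modulation", {
  fs <- 250
  n <- 20 * fs
  t <- (0:(n - 1)) / fs
  fam <- buildWaveletFamily(6, 12, 0.35, 0.5, fs)
  i9 <- which.min(abs(fam@foi - 9))
  set.seed(4)
  m <- as.numeric(stats::filter(rnorm(n), rep(1, fs) / fs,
                                circular = TRUE))
  env <- 1 + tanh(3 * m)
  sig <- array(0, c(1, 2, n))
  sig[1, 1, ] <- env * sin(2 * pi * 9 * t)
  sig[1, 2, ] <- env * sin(2 * pi * 9 * t + 2.1)
  ec <- computeEnvCorr(convolveEpochs(sig, fam))
  expect_gt(ec[i9, 1, 2], 0.5)
  expect_equal(ec[i9, 1, 1], 1)

  ind <- array(rnorm(2 * n), c(1, 2, n))
  ecI <- computeEnvCorr(convolveEpochs(ind, fam))
  expect_lt(abs(ecI[i9, 1, 2]), 0.15)

  # positive rescaling shifts the log envelope, Pearson unchanged
  sc <- sig
  sc[1, 2, ] <- 5 * sc[1, 2, ]
  ecS <- computeEnvCorr(convolveEpochs(sc, fam))
  expect_equal(ecS[i9, 1, 2], ec[i9, 1, 2], tolerance = 1e-8)
})

test_that("node strength averages off-diagonal rows with NA masking", {
  M <- matrix(0, 3, 3)
  M[upper.tri(M)] <- c(0.1, 0.2, 0.3)
  M <- M + t(M)
  expect_equal(nodeStrength(M), c(0.15, 0.2, 0.25))
  C <- matrix(0.4, 4, 4)
  expect_equal(nodeStrength(C), rep(0.4, 4))
  M2 <- M
  M2[1, 2] <- NA; M2[2, 1] <- NA
  expect_equal(nodeStrength(M2)[1], 0.2) # mean of the remaining entry
  arr <- array(NA_real_, c(2, 3, 3))
  arr[1, , ] <- M; arr[2, , ] <- 2 * M
  ns <- nodeStrength(arr)
  expect_equal(dim(ns), c(3, 2))
  expect_equal(ns[, 2], 2 * ns[, 1])
})
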