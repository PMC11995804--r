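test_that("common-subspace projection preserves geometry at full rank", {
  set.seed(1)
  arr <- spdArray(5, 6)
  full <- commonSubspaceProject(arr, 6, reg = 0)
  D0 <- pairwiseAirm(arr)
  D1 <- pairwiseAirm(full)
  # congruence by an orthogonal matrix leaves AIRM distances unchanged
  expect_equal(D1, D0, tolerance = 1e-8)

  # a rank-1 projection of diagonal matrices picks the dominant entry
  dg <- array(0, c(4, 3, 3))
  for (i in 1:4) dg[i, , ] <- diag(c(5, 1, 0.5) * (1 + 0.1 * i))
  r1 <- commonSubspaceProject(dg, 1, reg = 0)
  expect_equal(drop(r1@matrices),
               vapply(1:4, function(i) dg[i, 1, 1], 1.0),
               tolerance = 1e-8)

  # the study's rank reduction: 102 x 102 inputs -> 65 x 65
  set.seed(2)
  big <- spdArray(4, 102, df = 120)
  proj <- commonSubspaceProject(big, 65)
  expect_equal(dim(spdMatrices(proj)), c(4, 65, 65))
  expect_equal(dim(proj@filters), c(102, 65))
  for (i in 1:4) {
    ev <- eigen(proj@matrices[i, , ], symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("nearest-SPD repair matches the eigenvalue-clipping oracle", {
  m <- matrix(c(0, 1, 1, 0), 2)
  out <- nearestSPD(m)
  expect_equal(out, matrix(0.5, 2, 2) + diag(5e-16, 2),
               tolerance = 1e-12)
  # already SPD: unchanged up to the jitter
  set.seed(3)
  A <- randomSpd(4)
  expect_equal(nearestSPD(A), A, tolerance = 1e-10)
  expect_error(nearestSPD(matrix(c(1, NA, NA, 1), 2)), "non-finite")

  # Frobenius minimality among PSD matrices (dense 2x2 search)
  S <- matrix(c(1, 2, 2, -1), 2)
  best <- nearestSPD(S, reg = 0)
  dBest <- sqrt(sum((best - S)^2))
  grid <- seq(-3, 3, by = 0.15)
  viol <- 0L
  for (a in grid) for (b in grid) for (cc in seq(0, 3, by = 0.15)) {
    M <- matrix(c(a, b, b, cc), 2)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= 0 && sqrt(sum((M - S)^2)) < dBest - 1e-9)
      viol <- viol + 1L
  }
  expect_equal(viol, 0L)
})

test_that("AIRM distance obeys its closed forms and affine invariance", {
  p <- 5
  expect_equal(airmDistance(diag(p), diag(p)), 0)
  expect_equal(airmDistance(diag(p), 3 * diag(p)), sqrt(p) * log(3))
  set.seed(4)
  for (r in 1:5) {
    A <- randomSpd(4); B <- randomSpd(4)
    W <- matrix(rnorm(16), 4)
    d0 <- airmDistance(A, B)
    d1 <- airmDistance(W %*% A %*% t(W), W %*% B %*% t(W))
    expect_lt(abs(d1 - d0) / d0, 1e-8)
    expect_equal(airmDistance(B, A), d0, tolerance = 1e-10)
  }
  expect_error(airmDistance(diag(c(1, -1)), diag(2)), "positive definite")
})

test_that("Frechet mean and tangent embedding are locally Euclidean", {
  set.seed(5)
  A <- randomSpd(4)
  expect_equal(frechetMean(array(A, c(1, 4, 4))), A, tolerance = 1e-8)
  two <- array(0, c(2, 4, 4)); two[1, , ] <- A; two[2, , ] <- A
  expect_equal(frechetMean(two), A, tolerance = 1e-8)
  tv <- tangentVectors(two)
  expect_lt(max(abs(tv)), 1e-7)

  # first-order: M = G^(1/2) expm(S) G^(1/2) has tangent vector vec(S)
  G <- randomSpd(3)
  eG <- eigen(G, symmetric = TRUE)
  Gs <- eG$vectors %*% (sqrt(eG$values) * t(eG$vectors))
  S <- matrix(rnorm(9, sd = 0.01), 3); S <- (S + t(S)) / 2
  eS <- eigen(S, symmetric = TRUE)
  M <- Gs %*% (eS$vectors %*% (exp(eS$values) * t(eS$vectors))) %*% Gs
  arr <- array(0, c(1, 3, 3)); arr[1, , ] <- M
  tv1 <- tangentVectors(arr, ref = G)
  expected <- c(diag(S), sqrt(2) * S[upper.tri(S)])
  expect_equal(as.numeric(tv1), expected, tolerance = 1e-3)

  # local isometry: tangent Euclidean distance ~ AIRM distance
  base <- randomSpd(4)
  nearby <- array(0, c(6, 4, 4))
  for (i in 1:6) {
    E <- matrix(rnorm(16, sd = 0.005), 4)
    P <- base %*% E
    nearby[i, , ] <- base + (P + t(P)) / 2
  }
  tvN <- tangentVectors(nearby)
  for (i in 1:5) for (j in (i + 1):6) {
    dA <- airmDistance(nearby[i, , ], nearby[j, , ])
    dE <- sqrt(sum((tvN[i, ] - tvN[j, ])^2))
    if (dA > 1e-6 && dA < 0.1)
      expect_lt(abs(dE - dA) / dA, 0.05)
  }
})

test_that("pseudo-F agrees with the Euclidean MANOVA oracle", {
  skip_if_not_installed("vegan")
  set.seed(6)
  X <- matrix(rnorm(12 * 3), 12, 3)
  lab <- rep(c("a", "b"), each = 6)
  D <- as.matrix(dist(X))
  f <- distancePseudoF(D, lab)
  or <- vegan::adonis2(dist(X) ~ g, data = data.frame(g = lab),
                       permutations = 2)
  expect_equal(f, or$F[1], tolerance = 1e-10)
})

test_that("distance MANOVA saturates under separation and guards inputs", {
  set.seed(7)
  arr <- array(0, c(16, 3, 3))
  for (i in 1:8) arr[i, , ] <- randomSpd(3)
  for (i in 9:16) arr[i, , ] <- 1000 * randomSpd(3)
  lab <- rep(c("a", "b"), each = 8)
  mv <- distanceManova(arr, lab, nPerm = 199, seed = 1)
  expect_equal(mv$p, 1 / 200)
  expect_error(distanceManova(arr, rep("a", 16), nPerm = 10), "two groups")
  expect_error(distanceManova(arr[1:3, , ], c("a", "a", "b"), nPerm = 10),
               ">= 2")
})

test_that("frequency-wise MANOVA returns monotone FDR adjustment", {
  set.seed(8)
  mats <- lapply(1:8, function(i) {
    arr <- array(0, c(2, 4, 4))
    arr[1, , ] <- randomSpd(4)
    arr[2, , ] <- randomSpd(4)
    arr
  })
  # subjects x (freq, sensor, sensor): 8 subjects, 2 frequencies
  subj <- lapply(1:8, function(i) mats[[i]])
  res <- manovaByFrequency(subj, rep(c("a", "b"), 4), foi = c(2, 4),
                           rank = 4, nPerm = 99, seed = 3)
  expect_true(all(res$pFdr >= res$p))
  expect_true(all(res$p > 0 & res$p <= 1))
})
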