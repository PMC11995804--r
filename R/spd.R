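## Riemannian machinery for SPD matrix sets: common-subspace projection,
## nearest-SPD repair, affine-invariant distances, Frechet mean, tangent
## embedding and the distance MANOVA.

#' @noRd
symEigenFun <- function(M, fun) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (fun(e$values) * t(e$vectors))
}

matLog <- function(M) symEigenFun(M, log)
matExp <- function(M) symEigenFun(M, exp)
matInvSqrt <- function(M) symEigenFun(M, function(v) 1 / sqrt(v))
matSqrt <- function(M) symEigenFun(M, sqrt)

#' Project a set of symmetric matrices to a common subspace
#'
#' Spatial filters are the top-`rank` eigenvectors of the grand-average
#' matrix (eigenvector signs fixed so the largest-magnitude component is
#' positive); each matrix is mapped to `t(W) %*% M %*% W` and
#' regularized with `reg * trace/rank` on the diagonal. If any
#' projected matrix still has a non-positive eigenvalue, all matrices
#' receive the minimal common diagonal shift restoring strict positive
#' definiteness (recorded in the `reg` slot semantics).
#'
#' @param matrices n x p x p array (or list) of symmetric matrices.
#' @param rank target subspace dimension (<= p).
#' @param reg trace-scaled regularization scalar (default 1e-15).
#' @return an [SPDMatrixSet-class].
#' @export
commonSubspaceProject <- function(matrices, rank, reg = 1e-15) {
  if (is.list(matrices)) {
    p <- nrow(matrices[[1]])
    arr <- array(0, c(length(matrices), p, p))
    for (i in seq_along(matrices)) arr[i, , ] <- matrices[[i]]
    matrices <- arr
  }
  n <- dim(matrices)[1]; p <- dim(matrices)[2]
  if (rank > p) stop("rank must not exceed matrix dimension")
  G <- apply(matrices, c(2, 3), mean)
  if (max(abs(G - t(G))) > 1e-8 * max(abs(G), 1))
    stop("grand-average matrix is not symmetric")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  W <- e$vectors[, seq_len(rank), drop = FALSE]
  for (j in seq_len(rank)) { # deterministic sign convention
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  out <- array(0, c(n, rank, rank))
  minEig <- Inf
  for (i in seq_len(n)) {
    M <- t(W) %*% matrices[i, , ] %*% W
    M <- (M + t(M)) / 2
    M <- M + diag(reg * sum(diag(M)) / rank, rank)
    out[i, , ] <- M
    minEig <- min(minEig, min(eigen(M, symmetric = TRUE,
                                    only.values = TRUE)$values))
  }
  if (minEig <= 0) {
    shift <- -minEig + reg * mean(apply(out, 1, function(m)
      sum(diag(matrix(m, rank))))) / rank + .Machine$double.eps
    for (i in seq_len(n)) out[i, , ] <- out[i, , ] + diag(shift, rank)
  }
  new("SPDMatrixSet", matrices = out, rank = rank, reg = reg,
      filters = W)
}

#' Nearest symmetric positive-definite repair
#'
#' Symmetrizes, clips negative eigenvalues to zero (the Frobenius-
#' nearest PSD matrix) and adds `reg * trace/dim` jitter on the
#' diagonal so the result is strictly positive definite.
#'
#' @param m square matrix (missing entries must be filled beforehand).
#' @param reg trace-scaled jitter (default 1e-15).
#' @return SPD matrix of the same dimension.
#' @export
nearestSPD <- function(m, reg = 1e-15) {
  if (any(!is.finite(m))) stop("non-finite entries in input")
  d <- nrow(m)
  S <- (m + t(m)) / 2
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  out <- (out + t(out)) / 2
  jitter <- reg * max(sum(v), 1)
  out + diag(jitter / d, d)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta(A, B) = || logm(A^{-1/2} B A^{-1/2}) ||_F`, invariant under
#' any congruence `M -> W M t(W)` with invertible `W`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return nonnegative scalar.
#' @export
airmDistance <- function(A, B) {
  eA <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (min(eA$values) <= 0) stop("A is not positive definite")
  iS <- eA$vectors %*% (1 / sqrt(eA$values) * t(eA$vectors))
  W <- iS %*% B %*% iS
  ev <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("B is not positive definite")
  sqrt(sum(log(ev)^2))
}

#' Pairwise AIRM distance matrix for an SPD set
#'
#' @param x an [SPDMatrixSet-class] or an n x r x r array.
#' @return n x n symmetric distance matrix.
#' @export
pairwiseAirm <- function(x) {
  arr <- if (is(x, "SPDMatrixSet")) x@matrices else x
  n <- dim(arr)[1]; r <- dim(arr)[2]
  cube <- aperm(arr, c(2, 3, 1))
  pairwise_airm_cpp(array(cube, c(r, r, n)))
}

#' Frechet (geometric) mean of an SPD set
#'
#' Fixed-point iteration on the matrix-log barycentre:
#' `G <- G^{1/2} expm(mean logm(G^{-1/2} M_i G^{-1/2})) G^{1/2}`,
#' tolerance 1e-8 on the Frobenius norm of the mean log, at most
#' `maxIter` steps.
#'
#' @param x an [SPDMatrixSet-class] or n x r x r array.
#' @param tol,maxIter convergence controls.
#' @return SPD matrix.
#' @export
frechetMean <- function(x, tol = 1e-8, maxIter = 50) {
  arr <- if (is(x, "SPDMatrixSet")) x@matrices else x
  n <- dim(arr)[1]; r <- dim(arr)[2]
  G <- apply(arr, c(2, 3), mean)
  tau <- 1 # step size, halved whenever the step norm grows
  prevNorm <- Inf
  for (it in seq_len(maxIter)) {
    iS <- matInvSqrt(G)
    S <- matSqrt(G)
    L <- matrix(0, r, r)
    for (i in seq_len(n)) L <- L + matLog(iS %*% arr[i, , ] %*% iS)
    L <- L / n
    stepNorm <- sqrt(sum(L^2))
    if (stepNorm < tol) return(G)
    if (stepNorm > prevNorm && tau > 1 / 16) tau <- tau / 2
    prevNorm <- stepNorm
    G <- S %*% matExp(tau * L) %*% S
    G <- (G + t(G)) / 2
  }
  stop("Frechet mean did not converge in ", maxIter,
       " steps (last step norm ", format(prevNorm), ")")
}

#' Tangent-space embedding of an SPD set
#'
#' Whitens each matrix by the Frechet mean `G` (computed here, or
#' supplied - e.g. a training-fold mean), takes the matrix log and
#' vectorizes the upper triangle with off-diagonals scaled by sqrt(2)
#' so Euclidean norms match Frobenius norms.
#'
#' @param x an [SPDMatrixSet-class] or n x r x r array.
#' @param ref optional reference SPD matrix (Frechet mean by default).
#' @return n x (r (r + 1) / 2) feature matrix; the reference is
#'   attached as attribute `"ref"`.
#' @export
tangentVectors <- function(x, ref = NULL) {
  arr <- if (is(x, "SPDMatrixSet")) x@matrices else x
  n <- dim(arr)[1]; r <- dim(arr)[2]
  if (is.null(ref)) ref <- frechetMean(arr)
  iS <- matInvSqrt(ref)
  up <- upper.tri(matrix(0, r, r))
  out <- matrix(0, n, r * (r + 1) / 2)
  for (i in seq_len(n)) {
    L <- matLog(iS %*% arr[i, , ] %*% iS)
    out[i, ] <- c(diag(L), sqrt(2) * L[up])
  }
  attr(out, "ref") <- ref
  out
}

#' Pseudo-F statistic from a pairwise distance matrix
#'
#' Two-group decomposition of squared distances:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` from within-group
#' pairs, `pseudo-F = (SS_between/(g-1)) / (SS_within/(n-g))`.
#'
#' @param D n x n distance matrix.
#' @param labels group factor (two levels).
#' @return scalar pseudo-F.
#' @export
distancePseudoF <- function(D, labels) {
  labels <- as.factor(labels)
  n <- nrow(D)
  g <- nlevels(labels)
  D2 <- D^2
  ssTot <- sum(D2[upper.tri(D2)]) / n
  ssW <- 0
  for (lv in levels(labels)) {
    i <- which(labels == lv)
    ssW <- ssW + sum(D2[i, i][upper.tri(D2[i, i])]) / length(i)
  }
  ssB <- ssTot - ssW
  (ssB / (g - 1)) / (ssW / (n - g))
}

#' Distance MANOVA on one SPD matrix set
#'
#' Permutation test of group differences via the pseudo-F computed on
#' pairwise affine-invariant Riemannian distances;
#' `p = (b + 1)/(nPerm + 1)` where `b` counts permutations with a
#' pseudo-F at least as large as observed.
#'
#' @param x an [SPDMatrixSet-class] or n x r x r array.
#' @param labels two-group factor of length n, each group >= 2.
#' @param nPerm number of label permutations (default 1000).
#' @param seed RNG seed for the permutation stream.
#' @return list with `pseudoF`, `p`, `nPerm`.
#' @export
distanceManova <- function(x, labels, nPerm = 1000, seed = 1) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups required")
  if (any(table(labels) < 2)) stop("each group needs >= 2 subjects")
  D <- pairwiseAirm(x)
  f0 <- distancePseudoF(D, labels)
  b <- withLocalSeed(seed, {
    sum(vapply(seq_len(nPerm), function(i)
      distancePseudoF(D, sample(labels)), 1.0) >= f0)
  })
  list(pseudoF = f0, p = (b + 1) / (nPerm + 1), nPerm = nPerm)
}

#' Frequency-wise distance MANOVA over a cohort of matrix metrics
#'
#' For each frequency, builds the SPD set (rank projection for
#' covariance/envelope; zero-filled nearest-SPD repair then low-rank
#' projection for dwPLI), runs [distanceManova()] and adjusts p-values
#' across frequencies with Benjamini-Hochberg FDR.
#'
#' @param metricArrays list (one per subject) of freqs x sensors x
#'   sensors arrays.
#' @param labels two-group factor.
#' @param foi frequency axis.
#' @param rank subspace rank (65 for covariance/envelope, 5 for dwPLI).
#' @param reg trace-scaled regularization.
#' @param dwpli set `TRUE` for the dwPLI path (NA fill + nearest-SPD).
#' @param nPerm,seed permutation controls.
#' @return data.frame: freq, pseudoF, p, pFdr.
#' @export
manovaByFrequency <- function(metricArrays, labels, foi, rank,
                              reg = 1e-15, dwpli = FALSE, nPerm = 1000,
                              seed = 1) {
  nF <- length(foi)
  n <- length(metricArrays)
  res <- data.frame(freq = foi, pseudoF = NA_real_, p = NA_real_)
  for (f in seq_len(nF)) {
    p <- dim(metricArrays[[1]])[2]
    arr <- array(0, c(n, p, p))
    for (i in seq_len(n)) {
      M <- metricArrays[[i]][f, , ]
      if (dwpli) {
        M[is.na(M)] <- 0
        M <- nearestSPD(M, reg)
      }
      arr[i, , ] <- M
    }
    set <- commonSubspaceProject(arr, rank, reg)
    mv <- distanceManova(set, labels, nPerm, seed = seed + f)
    res$pseudoF[f] <- mv$pseudoF
    res$p[f] <- mv$p
  }
  res$pFdr <- p.adjust(res$p, "BH")
  res
}
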