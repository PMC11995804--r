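## Mass-univariate group inference across frequency (and sensor x
## frequency) with TFCE permutation correction.

#' Two-sample pooled t statistics per column
#' @noRd
tstatCols <- function(X, idxA, idxB) {
  nA <- length(idxA); nB <- length(idxB)
  mA <- colMeans(X[idxA, , drop = FALSE])
  mB <- colMeans(X[idxB, , drop = FALSE])
  vA <- apply(X[idxA, , drop = FALSE], 2, var)
  vB <- apply(X[idxB, , drop = FALSE], 2, var)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[se == 0 & mA == mB] <- 0
  t
}

#' Bootstrap confidence interval for the per-frequency mean difference
#'
#' Percentile bootstrap of `mean(A) - mean(B)` per column; groups are
#' resampled independently with replacement.
#'
#' @param groupA,groupB subjects x freqs matrices.
#' @param nBoot bootstrap iterations (default 9999); a diagnostic
#'   warning is emitted below 100.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return data.frame: freq index, diff, lower, upper.
#' @export
bootstrapMeanDiff <- function(groupA, groupB, nBoot = 9999,
                              conf = 0.95, seed = 1) {
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("each group needs >= 2 subjects")
  if (nBoot < 100) warning("nBoot < 100: intervals will be unstable")
  obs <- colMeans(groupA) - colMeans(groupB)
  withLocalSeed(seed, {
    P <- ncol(groupA)
    boots <- matrix(0, nBoot, P)
    for (b in seq_len(nBoot)) {
      iA <- sample.int(nrow(groupA), replace = TRUE)
      iB <- sample.int(nrow(groupB), replace = TRUE)
      boots[b, ] <- colMeans(groupA[iA, , drop = FALSE]) -
        colMeans(groupB[iB, , drop = FALSE])
    }
    a <- (1 - conf) / 2
    data.frame(freq = seq_len(P), diff = obs,
               lower = apply(boots, 2, quantile, a),
               upper = apply(boots, 2, quantile, 1 - a))
  })
}

#' Uncorrected per-frequency permutation p-values
#'
#' Two-sided label-permutation test of the mean difference per column,
#' with the `(b + 1)/(nPerm + 1)` convention.
#'
#' @param groupA,groupB subjects x freqs matrices.
#' @param nPerm permutations (default 9999).
#' @param seed RNG seed.
#' @return numeric vector of p-values.
#' @export
permutationPUncorrected <- function(groupA, groupB, nPerm = 9999,
                                    seed = 1) {
  X <- rbind(groupA, groupB)
  nA <- nrow(groupA); n <- nrow(X)
  obs <- abs(colMeans(groupA) - colMeans(groupB))
  withLocalSeed(seed, {
    counts <- rep(0L, ncol(X))
    for (b in seq_len(nPerm)) {
      i <- sample.int(n, nA)
      d <- abs(colMeans(X[i, , drop = FALSE]) -
               colMeans(X[-i, , drop = FALSE]))
      counts <- counts + (d >= obs)
    }
    (counts + 1) / (nPerm + 1)
  })
}

#' Pointwise two-group F map
#'
#' One-way two-group F statistic per point, equal to the squared
#' pooled-variance t. Points with zero within-group variance are capped
#' at a large finite value with a warning.
#'
#' @param groupA,groupB subjects x points matrices.
#' @return numeric vector of F values.
#' @export
pointwiseF <- function(groupA, groupB) {
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("each group needs >= 2 subjects")
  X <- rbind(groupA, groupB)
  t <- tstatCols(X, seq_len(nrow(groupA)),
                 nrow(groupA) + seq_len(nrow(groupB)))
  f <- t^2
  if (any(!is.finite(f))) {
    warning("zero within-group variance: F capped")
    f[!is.finite(f)] <- .Machine$double.xmax^0.25
  }
  f
}

#' Graph edges for TFCE connectivity
#'
#' 1-D: neighbouring frequencies. 2-D (sensor x frequency): two points
#' are adjacent iff same frequency and adjacent sensors, or same sensor
#' and neighbouring frequency. Node index is `(f - 1) * nSensors + s`.
#' @noRd
tfceEdges <- function(nSensors, nFreq, adjacency = NULL) {
  if (is.null(adjacency)) { # 1-D chain over frequencies
    if (nFreq < 2) return(matrix(integer(0), 0, 2))
    return(cbind(seq_len(nFreq - 1) - 1L, seq_len(nFreq) [-1] - 1L))
  }
  edges <- list(); k <- 1
  ij <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  for (f in seq_len(nFreq)) {
    off <- (f - 1L) * nSensors
    if (nrow(ij))
      edges[[k]] <- cbind(off + ij[, 1] - 1L, off + ij[, 2] - 1L)
    k <- k + 1
    if (f < nFreq) {
      edges[[k]] <- cbind(off + seq_len(nSensors) - 1L,
                          off + nSensors + seq_len(nSensors) - 1L)
      k <- k + 1
    }
  }
  do.call(rbind, edges)
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' `TFCE(p) = sum_h extent(cluster(p, h))^E * h^H * dh` over `nSteps`
#' height steps of `dh = max/nSteps`, with clusters defined by
#' frequency-neighbour connectivity (vector input) or sensor-adjacency
#' x neighbouring-frequency connectivity (matrix input).
#'
#' @param statmap nonnegative vector (freqs) or sensors x freqs matrix.
#' @param E,H extent and height exponents (defaults 0.5 and 2).
#' @param nSteps number of height steps (dh = max/nSteps).
#' @param adjacency sensor adjacency matrix, required for matrix input.
#' @return enhanced map, same shape as the input.
#' @export
tfceEnhance <- function(statmap, E = 0.5, H = 2, nSteps = 50,
                        adjacency = NULL) {
  if (any(statmap < 0)) stop("statmap must be nonnegative")
  if (is.matrix(statmap)) {
    if (is.null(adjacency))
      stop("sensor adjacency required for a 2-D map")
    edges <- tfceEdges(nrow(statmap), ncol(statmap), adjacency)
    out <- tfce_enhance_cpp(as.numeric(statmap), edges, E, H, nSteps)
    return(matrix(out, nrow(statmap), ncol(statmap)))
  }
  edges <- tfceEdges(1L, length(statmap), NULL)
  tfce_enhance_cpp(as.numeric(statmap), edges, E, H, nSteps)
}

#' TFCE permutation test (two-tailed)
#'
#' Computes the signed t-map, enhances positive and negative parts
#' separately, and compares each point's |TFCE| against the null
#' distribution of the permutation maximum (max-statistic correction,
#' `(b + 1)/(nPerm + 1)` convention). Optional covariates are removed
#' by per-point linear residualization before testing.
#'
#' @param data subjects x freqs matrix, or subjects x sensors x freqs
#'   array (then `adjacency` is required).
#' @param labels two-group factor of length n.
#' @param E,H,nSteps TFCE parameters (defaults E = 0.5, H = 2, 50
#'   steps).
#' @param nPerm label permutations (default 1000; diagnostic warning
#'   below 100).
#' @param adjacency sensor adjacency for the 2-D case.
#' @param covariates optional data.frame of per-subject nuisance
#'   variables (e.g. MMSE, site) residualized out pointwise.
#' @param alpha significance level for `sigMask`.
#' @param seed RNG seed.
#' @return a [ClusterTestResult-class].
#' @export
tfcePermutationTest <- function(data, labels, E = 0.5, H = 2,
                                nSteps = 50, nPerm = 1000,
                                adjacency = NULL, covariates = NULL,
                                alpha = 0.05, seed = 1) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups required")
  if (nPerm < 100) warning("nPerm < 100: p-values will be coarse")
  is2d <- length(dim(data)) == 3
  if (is2d) {
    if (is.null(adjacency))
      stop("sensor adjacency required for sensor x frequency data")
    nS <- dim(data)[2]; nF <- dim(data)[3]
    X <- matrix(data, nrow = dim(data)[1]) # column = (f-1)*nS + s
  } else {
    nS <- 1L; nF <- ncol(data)
    X <- data
  }
  if (!is.null(covariates)) {
    M <- stats::model.matrix(~ ., data = covariates)
    X <- stats::lm.fit(M, X)$residuals
  }
  edges <- tfceEdges(nS, nF, if (is2d) adjacency else NULL)
  idxA0 <- which(labels == levels(labels)[1])
  idxB0 <- which(labels == levels(labels)[2])
  enhance2 <- function(t) {
    tfce_enhance_cpp(pmax(t, 0), edges, E, H, nSteps) +
      tfce_enhance_cpp(pmax(-t, 0), edges, E, H, nSteps)
  }
  tObs <- tstatCols(X, idxA0, idxB0)
  tfceObs <- enhance2(tObs)
  n <- nrow(X); nA <- length(idxA0)
  nullMax <- withLocalSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      i <- sample.int(n, nA)
      max(enhance2(tstatCols(X, i, setdiff(seq_len(n), i))))
    }, 1.0)
  })
  pCorr <- vapply(tfceObs, function(v)
    (sum(nullMax >= v) + 1) / (nPerm + 1), 1.0)
  shape <- function(v) if (is2d) matrix(v, nS, nF) else v
  new("ClusterTestResult",
      stat = shape(tObs), tfce = shape(tfceObs),
      pCorrected = shape(pCorr), sigMask = shape(pCorr <= alpha),
      E = E, H = H, nPerm = nPerm, alpha = alpha)
}
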