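## Conditional permutation importance of the second-layer inputs, with
## the Nadeau-Bengio corrected test over CV splits.

logLoss <- function(y, p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Conditionally permuted column
#'
#' Regresses column `j` of the score matrix on the remaining columns
#' (ridge, penalty chosen by GCV over the standard grid) using training
#' rows only, then replaces the test-row values by prediction plus
#' permuted residuals - destroying only the information in `j` not
#' shared with the other columns.
#'
#' @param scores subjects x variables matrix.
#' @param j column index to perturb.
#' @param trainRows,testRows row indices.
#' @param perm permutation of `seq_along(testRows)` (identity
#'   reproduces the original column); random if `NULL`.
#' @param lambdas penalty grid.
#' @return perturbed test-row column j.
#' @export
conditionalPermutation <- function(scores, j, trainRows, testRows,
                                   perm = NULL,
                                   lambdas = lambdaGrid()) {
  if (j < 1 || j > ncol(scores)) stop("variable index out of range")
  fit <- firstLayerRidgeReg(scores[trainRows, -j, drop = FALSE],
                            scores[trainRows, j], lambdas)
  pred <- predictRidgeReg(fit, scores[testRows, -j, drop = FALSE])
  resid <- scores[testRows, j] - pred
  if (is.null(perm)) perm <- sample.int(length(testRows))
  pred + resid[perm]
}

#' Per-split conditional permutation importance scores
#'
#' For every CV split of a fitted stack, the increase in second-layer
#' log loss when each variable's conditional residuals are permuted on
#' the test fold (`nPerm` draws, residual model fitted on training
#' rows).
#'
#' @param stack a [StackingResult-class] with artifacts.
#' @param nPerm permutations per split (default 500).
#' @param seed RNG seed.
#' @param lambdas penalty grid for the residual model.
#' @return splits x variables matrix of mean log-loss increases.
#' @export
cpiScores <- function(stack, nPerm = 500, seed = 1,
                      lambdas = lambdaGrid()) {
  arts <- Filter(Negate(is.null), stack@artifacts)
  if (!length(arts)) stop("stacking artifacts missing: refit the stack")
  vars <- setdiff(stack@models, "stack")
  out <- matrix(NA_real_, length(arts), length(vars),
                dimnames = list(NULL, vars))
  withLocalSeed(seed, {
    for (s in seq_along(arts)) {
      a <- arts[[s]]
      S <- a$scores
      y <- a$yTest
      co <- coef(a$model$cv, s = a$model$lambda)
      beta <- as.numeric(co)[-1]
      b0 <- as.numeric(co)[1]
      probs <- function(M) stats::plogis(drop(M %*% beta) + b0)
      test <- a$test
      loss0 <- logLoss(y, probs(S[test, , drop = FALSE]))
      for (k in seq_along(vars)) {
        fit <- firstLayerRidgeReg(S[a$train, -k, drop = FALSE],
                                  S[a$train, k], lambdas)
        pred <- predictRidgeReg(fit, S[test, -k, drop = FALSE])
        resid <- S[test, k] - pred
        dl <- vapply(seq_len(nPerm), function(b) {
          M <- S[test, , drop = FALSE]
          M[, k] <- pred + resid[sample.int(length(test))]
          logLoss(y, probs(M)) - loss0
        }, 1.0)
        out[s, k] <- mean(dl)
      }
    }
  })
  out
}

#' Nadeau-Bengio corrected t-test on CV scores
#'
#' `t = mean / sqrt((1/K + rho) var)` with `rho = nTest/nTrain =
#' 1/(nFolds - 1)` for k-fold CV, `df = K - 1`, one-sided upper-tail p
#' (a removed predictor is expected to worsen the loss).
#'
#' @param scores per-split scores (length `K = nFolds * nRepeats`).
#' @param nFolds,nRepeats the CV scheme.
#' @return list: t, df, p, rho.
#' @export
nadeauBengioTest <- function(scores, nFolds, nRepeats) {
  scores <- scores[is.finite(scores)]
  K <- length(scores)
  rho <- 1 / (nFolds - 1)
  v <- var(scores)
  m <- mean(scores)
  if (v == 0) {
    warning("zero variance across splits")
    return(list(t = if (m > 0) Inf else -Inf, df = K - 1,
                p = if (m > 0) 0 else 1, rho = rho))
  }
  t <- m / sqrt((1 / K + rho) * v)
  list(t = t, df = K - 1, p = pt(t, K - 1, lower.tail = FALSE),
       rho = rho)
}

#' CPI summary table
#'
#' @param stack a [StackingResult-class].
#' @param nPerm permutations per split.
#' @param seed RNG seed.
#' @return data.frame: variable, meanDelta, sd, t, p (no multiplicity
#'   correction - the statistic is conditionally self-controlling).
#' @export
cpiTable <- function(stack, nPerm = 500, seed = 1) {
  sc <- cpiScores(stack, nPerm, seed)
  nFolds <- stack@config$nFolds
  nRepeats <- stack@config$nRepeats
  res <- data.frame(variable = colnames(sc),
                    meanDelta = colMeans(sc, na.rm = TRUE),
                    sd = apply(sc, 2, sd, na.rm = TRUE))
  tests <- lapply(seq_len(ncol(sc)), function(k)
    nadeauBengioTest(sc[, k], nFolds, nRepeats))
  res$t <- vapply(tests, `[[`, 1.0, "t")
  res$p <- vapply(tests, `[[`, 1.0, "p")
  rownames(res) <- NULL
  res
}
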