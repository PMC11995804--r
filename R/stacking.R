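## Cross-fitted stacking: modality-specific first-layer ridge
## classifiers combined by a second-layer regularized logistic model
## under repeated, stratified cross-validation.

#' The standard regularization grid
#'
#' 50 values on a logarithmic grid between 1e-3 and 1e5, shared by the
#' first-layer ridge classifiers, the second-layer logistic model and
#' the CPI interpolation ridge.
#'
#' @param n number of grid points.
#' @export
lambdaGrid <- function(n = 50) 10^seq(-3, 5, length.out = n)

#' Stacking configuration
#'
#' @param nRepeats,nFolds repeated k-fold scheme (default 10 x 10 =
#'   100 splits).
#' @param stride keep every `stride`-th wavelet frequency (default 4:
#'   31 of 121).
#' @param rank tangent-space rank for covariance/envelope blocks
#'   (default 65, reduced to the sensor count if smaller).
#' @param reg trace-scaled SPD regularization.
#' @param lambdas regularization grid.
#' @param seed RNG seed for fold assignment.
#' @export
stackingConfig <- function(nRepeats = 10, nFolds = 10, stride = 4,
                           rank = 65, reg = 1e-15,
                           lambdas = lambdaGrid(), seed = 1) {
  list(nRepeats = nRepeats, nFolds = nFolds, stride = stride,
       rank = rank, reg = reg, lambdas = lambdas, seed = seed)
}

#' Feature and parameter counts of the stacked model
#'
#' The bookkeeping behind the feature layout: each MEG metric enters as
#' a full sensors x sensors matrix at every strided frequency
#' (`p^2 * nFreq` inputs); covariance and envelope blocks are embedded
#' in a rank-r tangent space whose cross-term count is
#' `r (r - 1)/2 * nFreq`; dwPLI is vectorized by its upper triangle
#' (`p (p - 1)/2 * nFreq`); the second layer sees one input per block.
#'
#' @param nSensors,rank,nFreq layout of the feature space.
#' @return list of counts.
#' @export
#' @examples
#' stackingFeatureCounts(102, 65, 31) # 322524, 64480, 159681
stackingFeatureCounts <- function(nSensors = 102, rank = 65,
                                  nFreq = 31) {
  list(inputsPerMegMetric = nSensors^2 * nFreq,
       covTangentParams = rank * (rank - 1) / 2 * nFreq,
       dwpliUpperParams = nSensors * (nSensors - 1) / 2 * nFreq,
       mriParams = 64, secondLayerInputs = 9)
}

#' Indices of every stride-th frequency
#' @param nFreq grid size; @param stride step.
#' @export
strideFrequencies <- function(nFreq, stride = 4)
  seq(1, nFreq, by = stride)

## ---- first layer --------------------------------------------------------

#' L2-regularized least-squares classifier with internal GCV
#'
#' Ridge regression on +-1 targets; the penalty is chosen by
#' generalized cross-validation over the 50-value grid, computed
#' exactly from one SVD of the standardized training matrix. Constant
#' feature columns are dropped with a diagnostic message. Returns a
#' linear scorer (decision function).
#'
#' @param X training features (subjects x dims).
#' @param y two-level outcome (factor/0-1/logical); the second level
#'   maps to +1.
#' @param lambdas penalty grid.
#' @return list of class `"ridgeScorer"` with `predict(newX)` scores.
#' @export
firstLayerFit <- function(X, y, lambdas = lambdaGrid()) {
  X <- as.matrix(X)
  yy <- as.integer(as.factor(y)) # 1/2
  t <- ifelse(yy == 2, 1, -1)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- which(scl > 0)
  if (length(keep) < ncol(X))
    message(ncol(X) - length(keep), " constant feature column(s) dropped")
  if (!length(keep)) { # nothing informative: constant scorer
    out <- list(w = numeric(0), b = mean(t), ctr = ctr, scl = scl,
                keep = keep, lambda = NA_real_)
    class(out) <- "ridgeScorer"
    return(out)
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2,
              scl[keep], "/")
  n <- nrow(Xs)
  sv <- svd(Xs, nu = min(n, ncol(Xs)), nv = min(n, ncol(Xs)))
  d2 <- sv$d^2
  uty <- crossprod(sv$u, t - mean(t))
  gcv <- vapply(lambdas, function(l) {
    shrink <- d2 / (d2 + l)
    fit <- sv$u %*% (shrink * uty)
    df <- sum(shrink) + 1
    rss <- sum((t - mean(t) - fit)^2)
    n * rss / (n - min(df, n - 1))^2
  }, 1.0)
  l <- lambdas[which.min(gcv)]
  w <- sv$v %*% ((sv$d / (sv$d^2 + l)) * uty)
  out <- list(w = drop(w), b = mean(t), ctr = ctr, scl = scl,
              keep = keep, lambda = l)
  class(out) <- "ridgeScorer"
  out
}

#' @export
predict.ridgeScorer <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!length(object$keep)) return(rep(object$b, nrow(X)))
  Xs <- sweep(sweep(X[, object$keep, drop = FALSE], 2,
                    object$ctr[object$keep]), 2,
              object$scl[object$keep], "/")
  drop(Xs %*% object$w) + object$b
}

## ---- blocks -------------------------------------------------------------

#' Assemble the nine modality blocks
#'
#' Demographics enter as scalars (site and sex as 0/1); covariance and
#' envelope-correlation matrices at the strided frequencies are
#' rank-projected to a common subspace (fit on all subjects, as in the
#' frequency-wise MANOVA) and kept as SPD arrays for per-fold
#' tangent-space embedding; dwPLI is vectorized by its upper triangle;
#' MRI contributes the 64 regional volumes.
#'
#' @param tensorList list (per subject) of [SpectralTensors-class].
#' @param tab cohort table (may contain missing education/MMSE/MRI).
#' @param config a [stackingConfig()].
#' @return named list of modality blocks (`name`, `encoding`, `data`,
#'   `freqs`).
#' @export
buildBlocks <- function(tensorList, tab, config = stackingConfig()) {
  n <- length(tensorList)
  foi <- tensorList[[1]]@foi
  fIdx <- strideFrequencies(length(foi), config$stride)
  p <- length(tensorList[[1]]@sensorIds)
  rank <- min(config$rank, p)
  scalar <- function(name, x) list(name = name, encoding = "scalar",
                                   data = as.numeric(x), freqs = NULL)
  blocks <- list(
    site = scalar("site", tab$site == "CBU"),
    age = scalar("age", tab$age),
    sex = scalar("sex", tab$sex == "M"),
    education = scalar("education", tab$education),
    MMSE = scalar("MMSE", tab$mmse))

  spdPrep <- function(getter) {
    lapply(fIdx, function(f) {
      arr <- array(0, c(n, p, p))
      for (i in seq_len(n)) arr[i, , ] <- getter(tensorList[[i]], f)
      commonSubspaceProject(arr, rank, config$reg)@matrices
    })
  }
  blocks$MEG_cov <- list(name = "MEG_cov", encoding = "tangent",
                         data = spdPrep(function(tt, f) tt@cov[f, , ]),
                         freqs = foi[fIdx])
  blocks$MEG_env <- list(name = "MEG_env", encoding = "tangent",
                         data = spdPrep(function(tt, f) {
                           M <- tt@envCorr[f, , ]
                           M[is.na(M)] <- 0
                           diag(M) <- 1
                           M
                         }),
                         freqs = foi[fIdx])
  up <- upper.tri(matrix(0, p, p))
  dw <- do.call(cbind, lapply(fIdx, function(f) {
    t(vapply(tensorList, function(tt) {
      M <- tt@dwpli[f, , ]
      M[is.na(M)] <- 0
      M[up]
    }, numeric(sum(up))))
  }))
  blocks$MEG_dwpli <- list(name = "MEG_dwpli",
                           encoding = "upper_triangle", data = dw,
                           freqs = foi[fIdx])
  mriCols <- grep("^vol_", names(tab), value = TRUE)
  blocks$MRI_vol <- list(name = "MRI_vol", encoding = "raw",
                         data = as.matrix(tab[, mriCols]),
                         freqs = NULL)
  blocks
}

## ---- folds and leakage bookkeeping --------------------------------------

#' Stratified fold assignment for repeated k-fold CV
#'
#' @param labels outcome factor.
#' @param nFolds,nRepeats scheme.
#' @param seed RNG seed.
#' @return list (per repeat) of integer fold ids per subject.
#' @export
makeFolds <- function(labels, nFolds, nRepeats, seed = 1) {
  withLocalSeed(seed, {
    lapply(seq_len(nRepeats), function(r) {
      fold <- integer(length(labels))
      for (lv in unique(labels)) {
        i <- which(labels == lv)
        fold[i] <- sample(rep_len(seq_len(nFolds), length(i)))
      }
      fold
    })
  })
}

#' Assert a fold assignment is a valid partition
#'
#' Trips (hard error) when fold bookkeeping is corrupted - the
#' cross-fitting leakage guard.
#' @param foldId integer fold id per subject; @param nFolds expected
#'   fold count.
#' @export
checkFoldIntegrity <- function(foldId, nFolds) {
  if (any(is.na(foldId)) || any(foldId < 1 | foldId > nFolds))
    stop("corrupted fold assignment: ids outside 1..nFolds")
  if (length(unique(foldId)) < 2)
    stop("corrupted fold assignment: fewer than 2 folds")
  invisible(TRUE)
}

## ---- iterative imputation -----------------------------------------------

#' Round-robin ridge imputation fitted on training rows only
#'
#' Each incomplete column is regressed on the others (ridge with GCV
#' penalty selection) using training rows where it is observed;
#' missing entries in all rows are replaced by predictions. Ten rounds
#' or a 1e-3 relative change stop the iteration. Columns entirely
#' missing in the training rows fall back to the training mean with a
#' diagnostic.
#'
#' @param X numeric matrix with missing values.
#' @param trainRows rows the imputer may learn from.
#' @param nRounds,tol iteration controls.
#' @param lambdas penalty grid.
#' @return list: `completed` matrix, `models` (per-column fit info).
#' @export
iterativeImpute <- function(X, trainRows, nRounds = 10, tol = 1e-3,
                            lambdas = lambdaGrid()) {
  X <- as.matrix(X)
  miss <- is.na(X)
  if (!any(miss)) return(list(completed = X, models = list()))
  comp <- X
  trMeans <- colMeans(X[trainRows, , drop = FALSE], na.rm = TRUE)
  trMeans[is.nan(trMeans)] <- 0
  for (j in seq_len(ncol(X)))
    comp[miss[, j], j] <- trMeans[j]
  incomplete <- which(colSums(miss) > 0)
  models <- list()
  for (r in seq_len(nRounds)) {
    delta <- 0
    for (j in incomplete) {
      obsTrain <- intersect(trainRows, which(!miss[, j]))
      if (!length(obsTrain)) {
        message("column ", j, " unobserved in training rows: mean fill")
        models[[as.character(j)]] <- list(mean = trMeans[j])
        next
      }
      fit <- firstLayerRidgeReg(comp[obsTrain, -j, drop = FALSE],
                                X[obsTrain, j], lambdas)
      models[[as.character(j)]] <- fit
      rows <- which(miss[, j])
      pred <- predictRidgeReg(fit, comp[rows, -j, drop = FALSE])
      delta <- max(delta, max(abs(pred - comp[rows, j]) /
                              (sd(X[obsTrain, j]) + 1e-12)))
      comp[rows, j] <- pred
    }
    if (delta < tol) break
  }
  list(completed = comp, models = models)
}

# plain ridge regression (continuous target) with GCV, shared by the
# imputer and the CPI interpolation model
firstLayerRidgeReg <- function(X, y, lambdas = lambdaGrid()) {
  X <- as.matrix(X)
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  keep <- which(scl > 0)
  if (!length(keep))
    return(list(w = numeric(0), b = mean(y), ctr = ctr, scl = scl,
                keep = keep))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2,
              scl[keep], "/")
  n <- nrow(Xs)
  sv <- svd(Xs)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, y - mean(y))
  gcv <- vapply(lambdas, function(l) {
    shrink <- d2 / (d2 + l)
    rss <- sum((y - mean(y) - sv$u %*% (shrink * uty))^2)
    df <- sum(shrink) + 1
    n * rss / (n - min(df, n - 1))^2
  }, 1.0)
  l <- lambdas[which.min(gcv)]
  w <- sv$v %*% ((sv$d / (sv$d^2 + l)) * uty)
  list(w = drop(w), b = mean(y), ctr = ctr, scl = scl, keep = keep,
       lambda = l)
}

predictRidgeReg <- function(fit, X) {
  X <- as.matrix(X)
  if (!length(fit$keep)) return(rep(fit$b, nrow(X)))
  Xs <- sweep(sweep(X[, fit$keep, drop = FALSE], 2,
                    fit$ctr[fit$keep]), 2, fit$scl[fit$keep], "/")
  drop(Xs %*% fit$w) + fit$b
}

## ---- cross-fitting ------------------------------------------------------

#' Block features for given training rows (leakage-safe)
#'
#' Tangent blocks use a Frechet mean computed on training subjects
#' only; scalar/raw blocks pass through (imputation happens on the
#' assembled scalar table upstream).
#' @noRd
blockFeatures <- function(block, trainRows) {
  if (block$encoding == "scalar")
    return(matrix(block$data, ncol = 1))
  if (block$encoding == "tangent") {
    feats <- lapply(block$data, function(arr) {
      ref <- frechetMean(arr[trainRows, , , drop = FALSE])
      tangentVectors(arr, ref)
    })
    return(do.call(cbind, feats))
  }
  as.matrix(block$data)
}

#' Cross-fitted first-layer scores for one CV repeat
#'
#' Every subject's score per block comes from a model never trained on
#' that subject; iterative imputation, standardization, tangent
#' references and first-layer fits all use training folds only.
#'
#' @param blocks output of [buildBlocks()].
#' @param labels outcome factor.
#' @param foldId integer fold assignment for this repeat.
#' @param lambdas penalty grid.
#' @return subjects x blocks score matrix (attribute `"foldId"`).
#' @export
crossFittedScores <- function(blocks, labels, foldId,
                              lambdas = lambdaGrid()) {
  nFolds <- max(foldId)
  checkFoldIntegrity(foldId, nFolds)
  n <- length(labels)
  scores <- matrix(NA_real_, n, length(blocks),
                   dimnames = list(NULL, names(blocks)))
  scalarNames <- names(blocks)[vapply(blocks, function(b)
    b$encoding == "scalar", TRUE)]
  scalarTab <- do.call(cbind, lapply(blocks[scalarNames],
                                     function(b) b$data))
  mriIdx <- which(vapply(blocks, function(b) b$name == "MRI_vol", TRUE))
  for (f in seq_len(nFolds)) {
    test <- which(foldId == f)
    train <- which(foldId != f)
    stopifnot(length(intersect(train, test)) == 0)
    # impute scalar covariates and MRI jointly on training rows
    imputable <- scalarTab
    if (length(mriIdx))
      imputable <- cbind(scalarTab, blocks[[mriIdx]]$data)
    imp <- iterativeImpute(imputable, train, lambdas = lambdas)$completed
    scalarDone <- imp[, seq_along(scalarNames), drop = FALSE]
    mriDone <- if (length(mriIdx))
      imp[, -seq_along(scalarNames), drop = FALSE] else NULL
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      Xb <- if (b$encoding == "scalar") {
        matrix(scalarDone[, match(names(blocks)[k], scalarNames)],
               ncol = 1)
      } else if (b$name == "MRI_vol") {
        mriDone
      } else {
        blockFeatures(b, train)
      }
      fit <- suppressMessages(
        firstLayerFit(Xb[train, , drop = FALSE], labels[train],
                      lambdas))
      scores[test, k] <- predict(fit, Xb[test, , drop = FALSE])
    }
  }
  stopifnot(!anyNA(scores))
  attr(scores, "foldId") <- foldId
  scores
}

## ---- second layer -------------------------------------------------------

#' Second-layer logistic combiner and per-split evaluation
#'
#' For every fold of every repeat, a regularized logistic model is
#' trained on the cross-fitted scores of the training subjects with
#' leave-one-group-out internal CV over the penalty grid (groups =
#' first-layer folds, so no subject's score is evaluated by a model
#' that saw it) and evaluated by AUC on the held-out fold. Marginal
#' single-block models are evaluated on identical splits. Folds whose
#' test set contains a single class are skipped and counted.
#'
#' @param blocks output of [buildBlocks()].
#' @param labels outcome factor (second level = positive class).
#' @param config a [stackingConfig()].
#' @return a [StackingResult-class].
#' @export
stackedClassifier <- function(blocks, labels, config = stackingConfig()) {
  labels <- as.factor(labels)
  y <- as.integer(labels) - 1L
  foldsAll <- makeFolds(labels, config$nFolds, config$nRepeats,
                        config$seed)
  modelNames <- c(names(blocks), "stack")
  aucs <- matrix(NA_real_, config$nRepeats * config$nFolds,
                 length(modelNames),
                 dimnames = list(NULL, modelNames))
  artifacts <- list()
  skipped <- 0
  row <- 0
  lastScores <- NULL
  for (r in seq_len(config$nRepeats)) {
    foldId <- foldsAll[[r]]
    scores <- crossFittedScores(blocks, labels, foldId,
                                config$lambdas)
    lastScores <- scores
    for (f in seq_len(config$nFolds)) {
      row <- row + 1
      test <- which(foldId == f)
      train <- which(foldId != f)
      if (length(unique(y[test])) < 2) {
        skipped <- skipped + 1
        next
      }
      for (k in seq_along(blocks))
        aucs[row, k] <- rocAuc(scores[test, k], y[test])
      fit2 <- secondLayerGlmnet(scores[train, , drop = FALSE],
                                y[train], foldId[train],
                                config$lambdas)
      pTest <- predictSecondLayer(fit2, scores[test, , drop = FALSE])
      aucs[row, "stack"] <- rocAuc(pTest, y[test])
      artifacts[[row]] <- list(repeatId = r, fold = f, test = test,
                               train = train, model = fit2,
                               scores = scores, yTest = y[test])
    }
  }
  new("StackingResult", aucs = aucs, models = modelNames,
      scoreMatrix = lastScores, foldIds = foldsAll,
      config = c(config, skippedSplits = skipped),
      artifacts = artifacts)
}

#' Second-layer stack from precomputed cross-fitted scores
#'
#' Runs only the second layer (per-fold regularized logistic combiner
#' with leave-one-group-out internal CV) on an existing subjects x
#' blocks score matrix - the path used when first-layer scores are
#' already cross-fitted, e.g. in calibration studies of the importance
#' statistics.
#'
#' @param scores subjects x blocks matrix of cross-fitted scores.
#' @param labels outcome factor (second level = positive class).
#' @param foldId integer fold assignment (the one used to cross-fit
#'   `scores`).
#' @param config a [stackingConfig()]; `nRepeats` is forced to 1.
#' @return a [StackingResult-class].
#' @export
stackFromScores <- function(scores, labels, foldId,
                            config = stackingConfig(nRepeats = 1)) {
  labels <- as.factor(labels)
  y <- as.integer(labels) - 1L
  nFolds <- max(foldId)
  checkFoldIntegrity(foldId, nFolds)
  modelNames <- c(colnames(scores), "stack")
  aucs <- matrix(NA_real_, nFolds, length(modelNames),
                 dimnames = list(NULL, modelNames))
  artifacts <- list()
  skipped <- 0
  for (f in seq_len(nFolds)) {
    test <- which(foldId == f)
    train <- which(foldId != f)
    if (length(unique(y[test])) < 2) {
      skipped <- skipped + 1
      next
    }
    for (k in seq_len(ncol(scores)))
      aucs[f, k] <- rocAuc(scores[test, k], y[test])
    fit2 <- secondLayerGlmnet(scores[train, , drop = FALSE], y[train],
                              foldId[train], config$lambdas)
    aucs[f, "stack"] <- rocAuc(
      predictSecondLayer(fit2, scores[test, , drop = FALSE]), y[test])
    artifacts[[f]] <- list(repeatId = 1L, fold = f, test = test,
                           train = train, model = fit2,
                           scores = scores, yTest = y[test])
  }
  cfg <- config
  cfg$nRepeats <- 1
  cfg$nFolds <- nFolds
  new("StackingResult", aucs = aucs, models = modelNames,
      scoreMatrix = scores, foldIds = list(foldId),
      config = c(cfg, skippedSplits = skipped), artifacts = artifacts)
}

# ridge logistic with leave-one-group-out CV over the lambda grid
secondLayerGlmnet <- function(X, y, groups, lambdas = lambdaGrid()) {
  foldid <- as.integer(as.factor(groups))
  lam <- sort(lambdas / nrow(X), decreasing = TRUE) # glmnet scaling
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = lam, foldid = foldid,
                          standardize = TRUE,
                          type.measure = "deviance")
  list(cv = cv, lambda = cv$lambda.min)
}

predictSecondLayer <- function(fit, X) {
  drop(predict(fit$cv, newx = as.matrix(X), s = fit$lambda,
               type = "response"))
}
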