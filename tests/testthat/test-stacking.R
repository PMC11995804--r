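test_that("feature bookkeeping reproduces the model's parameter counts", {
  counts <- stackingFeatureCounts(102, 65, 31)
  expect_equal(counts$inputsPerMegMetric, 322524)
  expect_equal(counts$covTangentParams, 64480)
  expect_equal(counts$dwpliUpperParams, 159681)
  expect_equal(counts$mriParams, 64)
  expect_equal(counts$secondLayerInputs, 9)
  expect_length(strideFrequencies(121, 4), 31)
  lg <- lambdaGrid()
  expect_length(lg, 50)
  expect_equal(range(lg), c(1e-3, 1e5))
})

test_that("the first-layer ridge scorer separates, shrinks and nulls", {
  set.seed(1)
  X <- rbind(matrix(rnorm(20 * 2, mean = 2), 20, 2),
             matrix(rnorm(20 * 2, mean = -2), 20, 2))
  y <- rep(c(1, 0), each = 20)
  fit <- firstLayerFit(X, y)
  expect_true(all(sign(predict(fit, X)) == ifelse(y == 1, 1, -1)))

  # lambda -> infinity: coefficients shrink, scores become constant
  fitBig <- firstLayerFit(X, y, lambdas = 1e12)
  expect_lt(sd(predict(fitBig, X)), 1e-6)

  # constant columns are dropped with a diagnostic
  Xc <- cbind(X, 1)
  expect_message(firstLayerFit(Xc, y), "constant feature")

  # pure noise: cross-fitted AUC near chance
  set.seed(2)
  aucs <- vapply(1:10, function(r) {
    Xn <- matrix(rnorm(60 * 30), 60, 30)
    yn <- rep(c(1, 0), each = 30)
    fold <- makeFolds(factor(yn), 5, 1, seed = r)[[1]]
    sc <- numeric(60)
    for (f in 1:5) {
      m <- firstLayerFit(Xn[fold != f, ], yn[fold != f])
      sc[fold == f] <- predict(m, Xn[fold == f, ])
    }
    rocAuc(sc, yn)
  }, 1.0)
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("cross-fitted scores have one column per block and are seeded", {
  px <- smallPlantedCohort()
  cfg <- stackingConfig(nRepeats = 1, nFolds = 5, stride = 2, rank = 6,
                        seed = 9)
  blocks <- buildBlocks(px$tens, px$tab, cfg)
  expect_length(blocks, 9)
  expect_setequal(names(blocks),
                  c("site", "age", "sex", "education", "MMSE",
                    "MEG_cov", "MEG_env", "MEG_dwpli", "MRI_vol"))
  labels <- factor(px$tab$group)
  fold <- makeFolds(labels, 5, 1, seed = 9)[[1]]
  s1 <- crossFittedScores(blocks, labels, fold, lambdaGrid(10))
  s2 <- crossFittedScores(blocks, labels, fold, lambdaGrid(10))
  expect_equal(ncol(s1), 9)
  expect_identical(s1, s2)
  expect_false(anyNA(s1))
})

test_that("corrupted fold bookkeeping trips the leakage assertion", {
  labels <- factor(rep(c("a", "b"), each = 10))
  expect_error(checkFoldIntegrity(c(rep(1:4, 5)), 5), NA)
  expect_error(checkFoldIntegrity(c(rep(1, 19), NA), 5), "corrupted")
  expect_error(checkFoldIntegrity(rep(7, 20), 5), "corrupted")
  expect_error(checkFoldIntegrity(rep(1, 20), 5), "fewer than 2")
  px <- smallPlantedCohort()
  cfg <- stackingConfig(nRepeats = 1, nFolds = 5, stride = 2, rank = 6)
  blocks <- buildBlocks(px$tens, px$tab, cfg)
  badFold <- rep(0L, nrow(px$tab))
  expect_error(crossFittedScores(blocks, factor(px$tab$group), badFold),
               "corrupted")
})

test_that("iterative imputation beats mean fill and never learns from test rows", {
  set.seed(3)
  n <- 120
  z <- rnorm(n)
  X <- cbind(a = z + rnorm(n, sd = 0.3), b = -z + rnorm(n, sd = 0.3),
             c = z + rnorm(n, sd = 0.3))
  truth <- X
  miss <- sample(n, 25)
  X[miss, "a"] <- NA
  train <- 1:80
  out <- iterativeImpute(X, train)
  expect_false(anyNA(out$completed))
  rmseIter <- sqrt(mean((out$completed[miss, "a"] - truth[miss, "a"])^2))
  mfill <- mean(X[train, "a"], na.rm = TRUE)
  rmseMean <- sqrt(mean((mfill - truth[miss, "a"])^2))
  expect_lt(rmseIter, rmseMean)
  # identity when complete
  expect_identical(iterativeImpute(truth, train)$completed, truth)
  # freeze: perturbing test rows changes no fitted parameter and no
  # imputed training-row value
  X2 <- X
  X2[81:120, c("b", "c")] <- X2[81:120, c("b", "c")] + 100
  out2 <- iterativeImpute(X2, train)
  expect_identical(out$models, out2$models)
  trainMiss <- intersect(miss, train)
  expect_identical(out$completed[trainMiss, "a"],
                   out2$completed[trainMiss, "a"])
})

test_that("the stack never loses much to noise blocks and nulls at chance", {
  set.seed(4)
  n <- 80
  y <- factor(rep(c("a", "b"), each = n / 2))
  yy <- as.integer(y) - 1
  mkScores <- function(informative) {
    sc <- matrix(rnorm(n * 9), n, 9,
                 dimnames = list(NULL, paste0("b", 1:9)))
    if (informative) sc[, 1] <- yy * 2 + rnorm(n)
    sc
  }
  gaps <- vapply(1:5, function(r) {
    fold <- makeFolds(y, 5, 1, seed = r)[[1]]
    m <- colMeans(stackFromScores(mkScores(TRUE), y, fold)@aucs,
                  na.rm = TRUE)
    m["stack"] - m["b1"]
  }, 1.0)
  expect_lt(abs(mean(gaps)), 0.05)
  fold <- makeFolds(y, 5, 1, seed = 1)[[1]]
  stNull <- stackFromScores(mkScores(FALSE), y, fold)
  expect_lt(abs(mean(stNull@aucs[, "stack"], na.rm = TRUE) - 0.5), 0.15)
})

test_that("two informative blocks synergize on average", {
  set.seed(5)
  gains <- vapply(1:20, function(r) {
    n <- 80
    y <- factor(rep(c("a", "b"), each = n / 2))
    yy <- as.integer(y) - 1
    sc <- matrix(rnorm(n * 9), n, 9,
                 dimnames = list(NULL, paste0("b", 1:9)))
    sc[, 1] <- yy * 1.2 + rnorm(n)
    sc[, 2] <- yy * 1.2 + rnorm(n)
    fold <- makeFolds(y, 5, 1, seed = r)[[1]]
    st <- stackFromScores(sc, y, fold)
    m <- colMeans(st@aucs, na.rm = TRUE)
    m["stack"] - max(m["b1"], m["b2"])
  }, 1.0)
  expect_gt(mean(gains), 0)
})
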