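test_that("cohort-description statistics reproduce the printed values", {
  expect_equal(chi2Yates(matrix(c(41, 23, 49, 4), 2, 2))$statistic,
               11.61, tolerance = 5e-3)
  expect_equal(chi2Yates(matrix(c(32, 20, 32, 33), 2, 2))$statistic,
               1.30, tolerance = 5e-3)
  prop <- matrix(c(20, 10, 40, 20), 2, 2) # proportional table
  expect_equal(chi2Yates(prop)$statistic, 0, tolerance = 0.2)
  expect_error(chi2Yates(matrix(c(0, 0, 3, 4), 2, 2)), "margins")
  expect_error(chi2Yates(matrix(c(1.5, 2, 3, 4), 2, 2)), "integers")

  expect_equal(pooledTFromSummary(25.54, 2.82, 64, 27.15, 2.41, 53)$t,
               -3.28, tolerance = 5e-3)
  expect_equal(pooledTFromSummary(73.99, 4.87, 90, 68.74, 8.48, 27)$t,
               4.07, tolerance = 5e-3)
  expect_equal(pooledTFromSummary(8.43, 4.47, 90, 13.02, 2.88, 27)$t,
               -5.02, tolerance = 5e-3)
  expect_equal(pooledTFromSummary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(pooledTFromSummary(1, 0, 10, 2, 1, 10), "deviations")
})

test_that("Harrell's rule caps the additive models at five predictors", {
  expect_equal(harrellCap(27), 5)
  d <- data.frame(group = rep(c("progression", "stable"), 10),
                  a = rnorm(20), b = rnorm(20), c = rnorm(20),
                  d = rnorm(20), e = rnorm(20), f = rnorm(20))
  expect_error(fitLogistic(d, c("a", "b", "c", "d", "e", "f")),
               "Harrell")
})

test_that("logistic fits match the closed-form Bernoulli likelihood", {
  y <- rep(c("progression", "stable"), c(64, 53))
  d <- data.frame(group = y)
  fit <- fitLogistic(d, character(0))
  aicExpected <- 2 - 2 * (64 * log(64 / 117) + 53 * log(53 / 117))
  expect_equal(fit$aic, aicExpected, tolerance = 1e-8)

  # perfect separation is named
  d2 <- data.frame(group = y, leak = as.integer(y == "progression"),
                   x = rnorm(117))
  expect_error(fitLogistic(d2, c("leak", "x")), "leak")

  # parameter recovery at n = 2000
  set.seed(1)
  n <- 2000
  X <- matrix(rnorm(3 * n), n, 3)
  beta <- c(0.8, -0.5, 0.2)
  p <- stats::plogis(drop(X %*% beta))
  d3 <- data.frame(group = ifelse(stats::rbinom(n, 1, p) == 1,
                                  "progression", "stable"),
                   x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
  fit3 <- fitLogistic(d3, c("x1", "x2", "x3"), standardize = FALSE)
  co <- fit3$coefficients
  for (j in 1:3)
    expect_lt(abs(co[j + 1, 1] - beta[j]), 3 * co[j + 1, 2])
})

test_that("average marginal effects match the finite-difference oracle", {
  set.seed(2)
  n <- 300
  d <- data.frame(group = ifelse(stats::rbinom(n, 1, 0.5) == 1,
                                 "progression", "stable"),
                  x1 = rnorm(n), x2 = rnorm(n))
  d$x1 <- d$x1 + (d$group == "progression")
  fit <- fitLogistic(d, c("x1", "x2"))
  ame <- averageMarginalEffects(fit)
  X <- fit$data
  h <- 1e-6
  for (v in c("x1", "x2")) {
    up <- X; up[[v]] <- up[[v]] + h
    dn <- X; dn[[v]] <- dn[[v]] - h
    fd <- mean((predict(fit$model, newdata = up, type = "response") -
                predict(fit$model, newdata = dn, type = "response")) /
               (2 * h))
    expect_equal(ame$ame[ame$variable == v], fd, tolerance = 1e-6)
  }
  # the logistic derivative at p = 0.5 gives AME = beta / 4
  b <- coef(fit$model)[["x1"]]
  pbar <- mean(predict(fit$model, type = "response") *
                 (1 - predict(fit$model, type = "response")))
  expect_equal(ame$ame[ame$variable == "x1"], b * pbar)
})

test_that("discrimination metrics reduce to the rank statistic", {
  y <- rep(c(1, 0), c(30, 25))
  expect_equal(rocAuc(y, y), 1)
  set.seed(3)
  s <- rnorm(55)
  u <- stats::wilcox.test(s[y == 1], s[y == 0])$statistic
  expect_equal(rocAuc(s, y), unname(u) / (30 * 25))
  # invariance under strictly monotone transforms
  expect_equal(rocAuc(exp(2 * s), y), rocAuc(s, y))

  # random scores: AUC near 1/2 with a covering bootstrap interval
  d <- data.frame(group = ifelse(y == 1, "progression", "stable"),
                  x = rnorm(55))
  fit <- fitLogistic(d, "x")
  disc <- discrimination(fit, nBoot = 200, seed = 4)
  expect_lt(abs(disc$auc - 0.5), 0.2)
  expect_true(disc$ci[1] <= disc$auc && disc$auc <= disc$ci[2])
  expect_gte(disc$sensYouden + disc$specYouden, 1)
})

test_that("paired AUC differences use shared bootstrap indices", {
  set.seed(5)
  n <- 80
  y <- rep(c("progression", "stable"), each = n / 2)
  d <- data.frame(group = y,
                  good = (y == "progression") + rnorm(n, sd = 0.8),
                  noise = rnorm(n))
  fitG <- fitLogistic(d, "good")
  fitN <- fitLogistic(d, "noise")
  cmp <- aucDifferenceBootstrap(fitG, fitN, nBoot = 200, seed = 6)
  expect_gt(cmp$diff, 0)
  expect_gt(cmp$propPositive, 0.9)
})

test_that("the cluster MEG power variable scales and falls back correctly", {
  set.seed(6)
  lay <- makeLayout(10, seed = 2)
  foi <- c(10, 16, 20, 30, 40)
  lp <- lapply(1:4, function(i) matrix(rnorm(10 * 5), 10, 5))
  v0 <- clusterMegPowerVariable(lp, foi, lay)
  expect_true(attr(v0, "fallback"))
  # globally doubled power: log10 psd shifts by log10(4) exactly
  lp2 <- lapply(lp, function(m) m + log10(4))
  v2 <- clusterMegPowerVariable(lp2, foi, lay)
  expect_equal(as.numeric(v2 - v0), rep(log10(4), 4))
  # a non-empty significance mask narrows the average
  sig <- matrix(FALSE, 10, 5)
  sig[which(posteriorMask(lay))[1], 3] <- TRUE
  ct <- new("ClusterTestResult", stat = sig * 1, tfce = sig * 1,
            pCorrected = 1 - sig, sigMask = sig, E = 0.5, H = 2,
            nPerm = 100, alpha = 0.05)
  v1 <- clusterMegPowerVariable(lp, foi, lay, ct)
  expect_false(attr(v1, "fallback"))
  expect_equal(as.numeric(v1),
               vapply(lp, function(m)
                 m[which(posteriorMask(lay))[1], 3], 1.0))
})

test_that("mean imputation leaves 104 subjects for the MRI models", {
  spec <- cohortSpec(seed = 8)
  tab <- cohortTable(injectMissingness(simulateCohort(spec,
                                                      signals = FALSE)))
  tab$cluster_meg_power <- rnorm(nrow(tab)) -
    0.5 * (tab$group == "progression")
  imp <- meanImpute(tab)
  expect_false(anyNA(imp$education))
  expect_equal(unique(imp$education[is.na(tab$education)]),
               mean(tab$education, na.rm = TRUE))
  # no gaps: identity
  expect_identical(meanImpute(imp), imp)
  fits <- fitRiskModels(tab)
  expect_equal(fits$aic$n[fits$aic$model == "model2"], 104)
  expect_equal(fits$aic$n[fits$aic$model == "model4"], 104)
  expect_equal(fits$aic$n[fits$aic$model == "model1"], 117)
  # nested-model identity: delta AIC = 2 dk - 2 dloglik
  dAic <- fits$model4$aic - fits$model2$aic
  expect_equal(dAic, 2 * 1 - 2 * (fits$model4$logLik -
                                    fits$model2$logLik),
               tolerance = 1e-10)
  tabAllNA <- tab
  tabAllNA$mmse <- NA_real_
  expect_error(meanImpute(tabAllNA), "entirely missing")
})
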