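## Additive logistic models of progression risk, cohort-description
## statistics, and discrimination metrics.

#' Yates-corrected chi-square for a 2 x 2 table
#'
#' @param tab 2 x 2 matrix of nonnegative integer counts, all margins
#'   positive.
#' @return list with `statistic`, `p`, `df = 1`.
#' @export
#' @examples
#' chi2Yates(matrix(c(41, 23, 49, 4), 2, 2))$statistic # ~11.61
chi2Yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("a 2 x 2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, df = 1)
}

#' Pooled-variance two-sample t from summary statistics
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' pooledTFromSummary(25.54, 2.82, 64, 27.15, 2.41, 53)$t # ~-3.28
pooledTFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Harrell's predictor cap
#'
#' `floor(frac * n)` of the smaller outcome class; with 27 subjects in
#' the smaller class at 20% this caps additive models at 5 predictors.
#'
#' @param nSmaller size of the smaller class.
#' @param frac fraction (default 0.2).
#' @export
harrellCap <- function(nSmaller, frac = 0.2) floor(nSmaller * frac)

#' Grand-mean imputation of education and MMSE
#'
#' Missing education and MMSE values are replaced by the mean over all
#' subjects with the value present. MRI columns are left untouched
#' (MRI-incomplete subjects are excluded from MRI models instead).
#'
#' @param tab cohort table.
#' @return the table with education/MMSE gaps filled.
#' @export
meanImpute <- function(tab) {
  for (v in c("education", "mmse")) {
    x <- tab[[v]]
    if (all(is.na(x))) stop("column ", v, " entirely missing")
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    tab[[v]] <- x
  }
  tab
}

#' Fit an additive logistic model of progression
#'
#' Predictors are z-scored (unless `standardize = FALSE`) and the model
#' is fit by iteratively reweighted least squares (convergence 1e-8,
#' at most 100 iterations). At most 5 non-site predictors are allowed
#' (Harrell's rule at the study's class sizes). Perfect separation is
#' detected and reported as an error naming the culprit predictor.
#'
#' @param data cohort table (must contain `group` plus the predictors;
#'   rows with missing predictors are dropped).
#' @param predictors character vector of column names; `"site"` and
#'   `"sex"` are entered as 0/1 indicators.
#' @param standardize z-score numeric predictors (default TRUE).
#' @return list of class `"riskFit"`: `model` (the glm), `coefficients`
#'   table, `logLik`, `aic`, `data` (the design actually used), `y`.
#' @export
fitLogistic <- function(data, predictors, standardize = TRUE) {
  if (length(setdiff(predictors, "site")) > 5)
    stop("more than 5 non-site predictors (Harrell's rule)")
  y <- as.integer(data$group == "progression")
  df <- data.frame(y = y)
  for (v in predictors) {
    x <- data[[v]]
    if (v == "site") x <- as.integer(x == "CBU")
    if (v == "sex") x <- as.integer(x == "M")
    df[[v]] <- as.numeric(x)
  }
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (standardize)
    for (v in predictors)
      if (sd(df[[v]]) > 0)
        df[[v]] <- (df[[v]] - mean(df[[v]])) / sd(df[[v]])
  fml <- if (length(predictors)) y ~ . else y ~ 1
  fit <- suppressWarnings(
    glm(fml, data = df, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)))
  co <- coef(fit)[-1]
  if (length(co) && (any(!is.finite(co)) || any(abs(co) > 15))) {
    culprit <- names(co)[which.max(abs(co))]
    stop("perfect separation detected; culprit predictor: ", culprit)
  }
  sm <- summary(fit)$coefficients
  structure(list(model = fit, coefficients = sm,
                 logLik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), data = df, y = df$y,
                 predictors = predictors),
            class = "riskFit")
}

#' @export
print.riskFit <- function(x, ...) {
  cat("Logistic risk model:", paste(x$predictors, collapse = " + "),
      "\n  AIC:", round(x$aic, 1), " logLik:", round(x$logLik, 2), "\n")
  invisible(x)
}

#' Average marginal effects of a logistic fit
#'
#' `AME_j = mean_i beta_j p_i (1 - p_i)` - the average change in
#' progression probability per (standardized) unit of predictor j,
#' conditional on the other variables. Standard errors by the delta
#' method; two-sided z-tests.
#'
#' @param fit a `"riskFit"` from [fitLogistic()].
#' @return data.frame: variable, ame, se, z, p.
#' @export
averageMarginalEffects <- function(fit) {
  p <- predict(fit$model, type = "response")
  w <- p * (1 - p)
  m <- mean(w)
  beta <- coef(fit$model)
  X <- stats::model.matrix(fit$model)
  V <- vcov(fit$model)
  vars <- names(beta)[-1]
  out <- data.frame(variable = vars, ame = NA_real_, se = NA_real_)
  dwd <- (1 - 2 * p) * w # d[p(1-p)]/d(linear predictor)
  for (j in vars) {
    ame <- beta[j] * m
    grad <- vapply(names(beta), function(k) {
      (k == j) * m + beta[j] * mean(dwd * X[, k])
    }, 1.0)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    out[out$variable == j, c("ame", "se")] <- c(ame, se)
  }
  out$z <- out$ame / out$se
  out$p <- 2 * pnorm(-abs(out$z))
  out
}

#' Rank-statistic ROC AUC
#'
#' @param scores numeric scores.
#' @param y 0/1 outcomes.
#' @return AUC in [0, 1] (normalized Mann-Whitney U).
#' @export
rocAuc <- function(scores, y) {
  r <- rank(scores)
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' In-sample discrimination with bootstrap confidence intervals
#'
#' Apparent ROC AUC of the fitted probabilities, with a percentile
#' bootstrap CI in which the model is re-fitted on every resample
#' (2000 iterations by default). Sensitivity/specificity are reported
#' both at the Youden-optimal threshold and at 0.5. Bootstrap
#' replicates that lose one class are redrawn and counted.
#'
#' @param fit a `"riskFit"`.
#' @param nBoot bootstrap iterations.
#' @param conf confidence level.
#' @param seed RNG seed (shared seeds make AUC differences comparable
#'   across models, see [aucDifferenceBootstrap()]).
#' @return list: auc, ci, sensYouden, specYouden, thresholdYouden,
#'   sens05, spec05, nRedrawn, bootAuc.
#' @export
discrimination <- function(fit, nBoot = 2000, conf = 0.95, seed = 1) {
  p <- predict(fit$model, type = "response")
  y <- fit$y
  auc <- rocAuc(p, y)
  thr <- sort(unique(p))
  sens <- vapply(thr, function(t) mean(p[y == 1] >= t), 1.0)
  spec <- vapply(thr, function(t) mean(p[y == 0] < t), 1.0)
  jbest <- which.max(sens + spec - 1)
  redrawn <- 0
  boot <- withLocalSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      repeat {
        i <- sample.int(length(y), replace = TRUE)
        if (length(unique(y[i])) == 2) break
        redrawn <<- redrawn + 1
      }
      d <- fit$data[i, , drop = FALSE]
      m <- suppressWarnings(glm(y ~ ., data = d, family = binomial(),
                                control = glm.control(epsilon = 1e-8,
                                                      maxit = 100)))
      rocAuc(predict(m, type = "response"), d$y)
    }, 1.0)
  })
  a <- (1 - conf) / 2
  list(auc = auc, ci = unname(quantile(boot, c(a, 1 - a))),
       sensYouden = sens[jbest], specYouden = spec[jbest],
       thresholdYouden = thr[jbest],
       sens05 = mean(p[y == 1] >= 0.5), spec05 = mean(p[y == 0] < 0.5),
       nRedrawn = redrawn, bootAuc = boot)
}

#' Paired bootstrap difference in AUC between two fitted models
#'
#' Both models are re-fitted on the same bootstrap indices (fixed
#' seed), making the AUC-difference distribution directly comparable.
#'
#' @param fitA,fitB `"riskFit"` objects on the same subjects.
#' @param nBoot iterations; @param conf level; @param seed shared seed.
#' @return list: diff, ci, propPositive.
#' @export
aucDifferenceBootstrap <- function(fitA, fitB, nBoot = 2000,
                                   conf = 0.95, seed = 1) {
  if (nrow(fitA$data) != nrow(fitB$data))
    stop("models must be fitted on the same subjects")
  y <- fitA$y
  refit <- function(fit, i) {
    d <- fit$data[i, , drop = FALSE]
    m <- suppressWarnings(glm(y ~ ., data = d, family = binomial(),
                              control = glm.control(epsilon = 1e-8,
                                                    maxit = 100)))
    rocAuc(predict(m, type = "response"), d$y)
  }
  diffs <- withLocalSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      repeat {
        i <- sample.int(length(y), replace = TRUE)
        if (length(unique(y[i])) == 2) break
      }
      refit(fitA, i) - refit(fitB, i)
    }, 1.0)
  })
  a <- (1 - conf) / 2
  list(diff = rocAuc(predict(fitA$model, type = "response"), y) -
         rocAuc(predict(fitB$model, type = "response"), y),
       ci = unname(quantile(diffs, c(a, 1 - a))),
       propPositive = mean(diffs > 0))
}

#' Per-subject cluster MEG power variable
#'
#' Mean log10 power over the (posterior and significant) sensor set and
#' the 16-38 Hz band. When the significance mask is empty (or no
#' cluster result is supplied) the variable falls back to the full
#' posterior mask x band, recorded in attribute `"fallback"`.
#'
#' @param logPsdList list (per subject) of sensors x freqs log10-power
#'   matrices.
#' @param foi frequency axis (Hz).
#' @param layout a [SensorLayout-class].
#' @param clusterResult optional [ClusterTestResult-class] with a
#'   sensors x freqs `sigMask`.
#' @param band frequency band in Hz (default c(16, 38)).
#' @return numeric vector (one value per subject) with attribute
#'   `"fallback"`.
#' @export
clusterMegPowerVariable <- function(logPsdList, foi, layout,
                                    clusterResult = NULL,
                                    band = c(16, 38)) {
  inBand <- foi >= band[1] & foi <= band[2]
  post <- layout@posteriorMask
  mask <- outer(post, inBand, "&")
  fallback <- TRUE
  if (!is.null(clusterResult) && is.matrix(clusterResult@sigMask)) {
    m2 <- clusterResult@sigMask & mask
    if (any(m2)) {
      mask <- m2
      fallback <- FALSE
    }
  }
  vals <- vapply(logPsdList, function(lp) mean(lp[mask]), 1.0)
  attr(vals, "fallback") <- fallback
  vals
}

#' The four additive risk models
#'
#' Model 1: age + education + MMSE; Model 2: + hippocampal ratio;
#' Model 3: Model 1 + cluster MEG power; Model 4: all five. Education
#' and MMSE gaps are mean-imputed; subjects with a missing MRI block
#' are excluded from Models 2 and 4 (no MRI imputation).
#'
#' @param tab cohort table with a `cluster_meg_power` column already
#'   attached.
#' @param withSite add site as a 0/1 indicator to every model
#'   (sensitivity analysis).
#' @return named list of `"riskFit"` objects plus an `aic` table.
#' @export
fitRiskModels <- function(tab, withSite = FALSE) {
  tab <- meanImpute(tab)
  base <- c("age", "education", "mmse")
  specs <- list(
    model1 = base,
    model2 = c(base, "hippocampal_ratio"),
    model3 = c(base, "cluster_meg_power"),
    model4 = c(base, "cluster_meg_power", "hippocampal_ratio"))
  if (withSite) specs <- lapply(specs, c, "site")
  fits <- lapply(specs, function(pr) fitLogistic(tab, pr))
  aic <- data.frame(model = names(fits),
                    aic = vapply(fits, `[[`, 1.0, "aic"),
                    n = vapply(fits, function(f) nrow(f$data), 1.0))
  c(fits, list(aic = aic))
}
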