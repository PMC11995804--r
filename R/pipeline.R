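## End-to-end orchestration: simulate -> features -> stats -> model ->
## classify -> cpi, with a manifest for reproducibility.

#' Default run configuration
#'
#' A compact end-to-end configuration (small cohort, coarse frequency
#' grid) suitable for examples and smoke runs; scale the fields up for
#' full-size analyses.
#'
#' @param seed global seed fanned out to per-stage substreams.
#' @export
defaultRunConfig <- function(seed = 1) {
  list(
    stages = c("simulate", "features", "stats", "model", "classify",
               "cpi"),
    cohort = list(nProg = 12, nStable = 10, nSensors = 16, nEpochs = 2,
                  epochLenS = 4, fs = 96,
                  missingCounts = list(education = 2, mmse = 1,
                                       mri = 2)),
    wavelet = list(fMin = 2, fMax = 40, bandwidthOct = 0.35,
                   samplingOct = 0.25),
    stats = list(nPerm = 200, E = 0.5, H = 2, alpha = 0.05,
                 manovaRank = 6, manovaPerm = 200),
    stacking = list(nRepeats = 2, nFolds = 5, stride = 2, rank = 6),
    cpi = list(nPerm = 50),
    seed = seed)
}

stageSeed <- function(config, stage) {
  offs <- c(simulate = 11, features = 23, stats = 37, model = 53,
            classify = 71, cpi = 89)
  (config$seed * 1009 + offs[[stage]]) %% 2147483647
}

#' Run the pipeline
#'
#' Executes the requested stages in order, writing result tables and a
#' manifest (config hash, package version, per-stage outputs and
#' wall-times) under `outDir`. Re-runs skip stages whose outputs exist
#' unless `force = TRUE`; a stage whose inputs are missing fails with
#' an error naming the missing artifact.
#'
#' @param config a configuration list, see [defaultRunConfig()].
#' @param outDir output directory.
#' @param force recompute completed stages.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir,
                        force = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(configHash = configHash(config),
                   package = as.character(utils::packageVersion("megprog")),
                   stages = list())
  paths <- list(
    cohort = file.path(outDir, "cohort"),
    features = file.path(outDir, "features.rds"),
    manova = file.path(outDir, "manova.csv"),
    cluster = file.path(outDir, "cluster.csv"),
    models = file.path(outDir, "models.csv"),
    ame = file.path(outDir, "ame.csv"),
    stacking = file.path(outDir, "stacking.json"),
    cpi = file.path(outDir, "cpi.csv"))

  done <- function(p) file.exists(p) && !force
  need <- function(p, stage) {
    if (!file.exists(p))
      stop("stage '", stage, "' needs missing artifact: ", p)
  }
  record <- function(stage, outs, t0) {
    manifest$stages[[stage]] <<- list(
      outputs = outs, seconds = round(as.numeric(Sys.time()) - t0, 2))
  }

  if ("simulate" %in% config$stages &&
      !(done(file.path(paths$cohort, "cohort.csv")))) {
    t0 <- as.numeric(Sys.time())
    spec <- do.call(cohortSpec,
                    c(config$cohort, seed = stageSeed(config, "simulate")))
    coh <- injectMissingness(simulateCohort(spec))
    writeCohort(coh, paths$cohort)
    record("simulate", paths$cohort, t0)
  }

  if ("features" %in% config$stages && !done(paths$features)) {
    t0 <- as.numeric(Sys.time())
    need(file.path(paths$cohort, "cohort.csv"), "features")
    coh <- readCohort(paths$cohort)
    fam <- do.call(buildWaveletFamily,
                   c(config$wavelet, fs = coh@spec@fs))
    tensors <- lapply(coh@table$subject_id, function(id)
      spectralFeatures(subjectSignals(coh, id), fam,
                       coh@layout@sensorIds))
    names(tensors) <- coh@table$subject_id
    saveRDS(tensors, paths$features)
    record("features", paths$features, t0)
  }

  if ("stats" %in% config$stages && !done(paths$manova)) {
    t0 <- as.numeric(Sys.time())
    need(paths$features, "stats")
    coh <- readCohort(paths$cohort)
    tensors <- readRDS(paths$features)
    labels <- factor(coh@table$group)
    covArrays <- lapply(tensors, function(tt) tt@cov)
    mv <- manovaByFrequency(covArrays, labels, tensors[[1]]@foi,
                            rank = config$stats$manovaRank,
                            nPerm = config$stats$manovaPerm,
                            seed = stageSeed(config, "stats"))
    write.csv(mv, paths$manova, row.names = FALSE)
    lp <- lapply(tensors, function(tt) tt@logPsd) # sensors x freqs
    arr <- array(0, c(length(lp), dim(lp[[1]])))
    for (i in seq_along(lp)) arr[i, , ] <- lp[[i]]
    ct <- tfcePermutationTest(arr, labels, E = config$stats$E,
                              H = config$stats$H,
                              nPerm = config$stats$nPerm,
                              adjacency = sensorAdjacency(coh@layout),
                              alpha = config$stats$alpha,
                              seed = stageSeed(config, "stats") + 1)
    cl <- data.frame(sensor = rep(coh@layout@sensorIds,
                                  length(tensors[[1]]@foi)),
                     freq = rep(tensors[[1]]@foi,
                                each = length(coh@layout@sensorIds)),
                     stat = as.numeric(ct@stat),
                     p_corrected = as.numeric(ct@pCorrected),
                     significant = as.numeric(ct@sigMask))
    write.csv(cl, paths$cluster, row.names = FALSE)
    record("stats", c(paths$manova, paths$cluster), t0)
  }

  if ("model" %in% config$stages && !done(paths$models)) {
    t0 <- as.numeric(Sys.time())
    need(paths$features, "model")
    coh <- readCohort(paths$cohort)
    tensors <- readRDS(paths$features)
    tab <- coh@table
    lp <- lapply(tensors, function(tt) tt@logPsd)
    tab$cluster_meg_power <- as.numeric(
      clusterMegPowerVariable(lp, tensors[[1]]@foi, coh@layout))
    fits <- fitRiskModels(tab)
    seedM <- stageSeed(config, "model")
    rows <- lapply(names(fits)[names(fits) != "aic"], function(nm) {
      d <- discrimination(fits[[nm]], nBoot = 200, seed = seedM)
      data.frame(model = nm, aic = fits[[nm]]$aic, auc = d$auc,
                 ci_lo = d$ci[1], ci_hi = d$ci[2],
                 sens = d$sensYouden, spec = d$specYouden)
    })
    write.csv(do.call(rbind, rows), paths$models, row.names = FALSE)
    ame <- averageMarginalEffects(fits$model4)
    write.csv(ame, paths$ame, row.names = FALSE)
    record("model", c(paths$models, paths$ame), t0)
  }

  if ("classify" %in% config$stages && !done(paths$stacking)) {
    t0 <- as.numeric(Sys.time())
    need(paths$features, "classify")
    coh <- readCohort(paths$cohort)
    tensors <- readRDS(paths$features)
    cfg <- do.call(stackingConfig,
                   c(config$stacking,
                     seed = stageSeed(config, "classify")))
    blocks <- buildBlocks(tensors, coh@table, cfg)
    stack <- stackedClassifier(blocks, factor(coh@table$group), cfg)
    jsonlite::write_json(
      list(models = stack@models,
           auc = apply(stack@aucs, 2, as.numeric, simplify = FALSE),
           mean_auc = as.list(colMeans(stack@aucs, na.rm = TRUE))),
      paths$stacking, auto_unbox = TRUE, digits = NA)
    saveRDS(stack, file.path(outDir, "stacking.rds"))
    record("classify", paths$stacking, t0)
  }

  if ("cpi" %in% config$stages && !done(paths$cpi)) {
    t0 <- as.numeric(Sys.time())
    stackFile <- file.path(outDir, "stacking.rds")
    need(stackFile, "cpi")
    stack <- readRDS(stackFile)
    tabCpi <- cpiTable(stack, nPerm = config$cpi$nPerm,
                       seed = stageSeed(config, "cpi"))
    write.csv(tabCpi, paths$cpi, row.names = FALSE)
    record("cpi", paths$cpi, t0)
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Hash of a configuration (for the run manifest)
#' @noRd
configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
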