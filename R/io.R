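#' Write a cohort to disk
#'
#' The covariate table goes to `cohort.csv` (one row per subject, empty
#' field = missing), the layout to `layout.json`, and each subject's
#' epoched signal array to `signals/<subject_id>.rds` together with its
#' sampling attributes.
#'
#' @param cohort a [MEGCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort@table, file.path(dir, "cohort.csv"),
            row.names = FALSE, na = "")
  lay <- cohort@layout
  jsonlite::write_json(list(
    sensor_ids = lay@sensorIds,
    positions = unname(apply(lay@positions, 1, as.numeric,
                             simplify = FALSE)),
    posterior_mask = lay@posteriorMask,
    adjacency = unname(apply(lay@adjacency, 1, as.logical,
                             simplify = FALSE))),
    file.path(dir, "layout.json"), auto_unbox = TRUE, digits = NA)
  if (length(cohort@signals)) {
    sdir <- file.path(dir, "signals")
    dir.create(sdir, showWarnings = FALSE)
    for (id in names(cohort@signals)) {
      x <- cohort@signals[[id]]
      attr(x, "fs") <- cohort@spec@fs
      attr(x, "epoch_len_s") <- cohort@spec@epochLenS
      attr(x, "sensor_ids") <- lay@sensorIds
      saveRDS(x, file.path(sdir, paste0(id, ".rds")))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `cohort.csv`, `layout.json` and
#'   optionally `signals/`.
#' @param spec the generating [CohortSpec-class] (kept with the object;
#'   a default spec matching the table size is built if omitted).
#' @return a [MEGCohort-class].
#' @export
readCohort <- function(dir, spec = NULL) {
  tab <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  lj <- jsonlite::read_json(file.path(dir, "layout.json"),
                            simplifyVector = TRUE)
  pos <- if (is.list(lj$positions))
    do.call(rbind, lapply(lj$positions, as.numeric)) else
      matrix(as.numeric(lj$positions), ncol = 2)
  colnames(pos) <- c("x", "y")
  rownames(pos) <- lj$sensor_ids
  A <- if (is.list(lj$adjacency))
    do.call(rbind, lapply(lj$adjacency, as.logical)) else
      matrix(as.logical(lj$adjacency), nrow = length(lj$sensor_ids))
  dimnames(A) <- list(lj$sensor_ids, lj$sensor_ids)
  layout <- new("SensorLayout", sensorIds = lj$sensor_ids,
                positions = pos, posteriorMask = lj$posterior_mask,
                adjacency = A)
  sdir <- file.path(dir, "signals")
  sigs <- list()
  fs <- NA; el <- NA
  if (dir.exists(sdir)) {
    for (id in tab$subject_id) {
      f <- file.path(sdir, paste0(id, ".rds"))
      if (file.exists(f)) {
        x <- readRDS(f)
        fs <- attr(x, "fs"); el <- attr(x, "epoch_len_s")
        sigs[[id]] <- x
      }
    }
  }
  if (is.null(spec)) {
    nP <- sum(tab$group == "progression")
    nS <- sum(tab$group == "stable")
    tt <- table(factor(tab$site, c("CTB", "CBU")),
                factor(tab$group, c("progression", "stable")))
    st <- matrix(as.integer(tt), 2, 2, dimnames = dimnames(tt))
    spec <- cohortSpec(nProg = nP, nStable = nS, siteTable = st,
                       nSensors = length(lj$sensor_ids),
                       nEpochs = if (length(sigs)) dim(sigs[[1]])[1] else 1,
                       epochLenS = if (is.na(el)) 1 else el,
                       fs = if (is.na(fs)) 250 else fs)
  }
  new("MEGCohort", table = tab, signals = sigs, layout = layout,
      spec = spec)
}
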