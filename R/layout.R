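#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded internals do
#' not disturb the global stream.
#' @noRd
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Build a synthetic magnetometer layout on the unit disc
#'
#' Sensors are placed on a sunflower (golden-angle) spiral with a small
#' seeded jitter, giving near-uniform coverage of the disc. The
#' parieto-occipital ("posterior") set is the lowest 30% of sensors by
#' y-coordinate. The adjacency relation connects sensors closer than a
#' distance threshold chosen so the mean neighbour count lies in 4-8
#' (capped for very small arrays); any sensor left with fewer than two
#' neighbours is linked to its two nearest sensors.
#'
#' @param nSensors number of sensors (>= 4); 102 mirrors a magnetometer
#'   array.
#' @param seed integer seed; the layout is a pure function of
#'   `(nSensors, seed)`.
#' @return a [SensorLayout-class].
#' @export
#' @examples
#' lay <- makeLayout(102, seed = 0)
#' mean(rowSums(sensorAdjacency(lay)))
makeLayout <- function(nSensors = 102, seed = 0) {
  if (nSensors < 4) stop("nSensors must be >= 4")
  withLocalSeed(seed, {
    i <- seq_len(nSensors)
    golden <- pi * (3 - sqrt(5))
    r <- sqrt((i - 0.5) / nSensors)
    theta <- i * golden + rnorm(nSensors, sd = 0.03)
    pos <- cbind(x = r * cos(theta), y = r * sin(theta))
    pos <- pos + matrix(rnorm(2 * nSensors, sd = 0.01), ncol = 2)

    posterior <- pos[, "y"] <= quantile(pos[, "y"], 0.3)

    D <- as.matrix(dist(pos))
    targetDeg <- min(6, nSensors - 1)
    dOff <- sort(D[upper.tri(D)])
    nEdges <- max(1, round(targetDeg * nSensors / 2))
    thr <- dOff[min(nEdges, length(dOff))]
    A <- D <= thr & D > 0
    # guarantee >= 2 neighbours per sensor
    for (s in which(rowSums(A) < 2)) {
      nb <- order(D[s, ])[2:3]
      A[s, nb] <- TRUE
      A[nb, s] <- TRUE
    }
    ids <- sprintf("MEG%03d", i)
    dimnames(A) <- list(ids, ids)
    rownames(pos) <- ids
    new("SensorLayout", sensorIds = ids, positions = pos,
        posteriorMask = unname(posterior), adjacency = A)
  })
}

#' Spatially smooth random field over sensor positions
#'
#' Gaussian-kernel-smoothed white noise; used as mixing vectors so that
#' simulated sources produce realistic field spread across neighbouring
#' sensors.
#' @noRd
smoothField <- function(positions, lengthScale = 0.4) {
  D2 <- as.matrix(dist(positions))^2
  K <- exp(-D2 / (2 * lengthScale^2))
  f <- drop(K %*% rnorm(nrow(positions)))
  f / sqrt(sum(f^2))
}
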