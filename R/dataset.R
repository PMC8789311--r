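#' Extract the feature vector of a simulated region
#'
#' Convenience wrapper: locates the local tree containing the focal site and
#' calls [extractFeatures()].
#'
#' @param region a [SimulatedRegion-class].
#' @param grid a [TimeGrid-class].
#' @param site focal [SiteLabel-class]; defaults to the region's own focal
#'   site (sweep regions). Neutral regions must supply one, usually from
#'   [pickNeutralFocalSite()].
#' @param nFlankPerSide,normalize passed to [extractFeatures()].
#' @return a [FeatureVector-class].
#' @export
regionFeatures <- function(region, grid, site = NULL, nFlankPerSide = 2L,
                           normalize = TRUE) {
  if (is.null(site)) site <- region@focalSite
  if (is.null(site)) stop("neutral regions need an explicit focal site")
  idx <- treeIndexAt(region, site@position)
  extractFeatures(region@trees, idx, site, grid,
                  nFlankPerSide = nFlankPerSide, normalize = normalize)
}

#' Generate a labeled training/validation/test dataset
#'
#' Simulates \code{nNeutral} neutral and \code{nSweep} sweep regions, extracts
#' the lineage-count feature of each focal site, and returns features plus
#' truth labels. Neutral focal sites are chosen DAF-matched: a target
#' frequency is drawn from the sweep prior's f range and a segregating site
#' with that frequency (within \code{dafTolerance}) is picked at random, so
#' class labels are not separable on present-day frequency alone. A master
#' seed fans out per-record child seeds (recorded in the metadata) so any
#' record can be regenerated independently.
#'
#' @param nNeutral,nSweep number of regions per class.
#' @param prior a [priorSpec()] for the sweep parameters.
#' @param demography a [DemographyModel-class].
#' @param L region length in bp.
#' @param n number of sampled haplotypes.
#' @param grid a [TimeGrid-class].
#' @param nFlankPerSide flanking trees per side.
#' @param seed master seed; \code{NULL} uses the current RNG state.
#' @param dafTolerance tolerance for neutral DAF matching.
#' @param maxRetries resimulation cap per record.
#' @param verbose print progress every 200 records.
#' @return a list of class \code{"sweepDataset"}: \code{features} (N x K x C
#'   array), \code{labels} (data.frame with class, mode, s, f, onset,
#'   nDerived), \code{trajectories} (N x K matrix of discretized truth
#'   trajectories; 0 rows where absent), and \code{meta}.
#' @export
makeDataset <- function(nNeutral, nSweep, prior = priorSpec(),
                        demography = demographyConstant(), L = 1e5, n = 198L,
                        grid = buildTimeGrid(), nFlankPerSide = 2L,
                        seed = NULL, dafTolerance = 0.02, maxRetries = 50L,
                        verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  N <- nNeutral + nSweep
  childSeeds <- sample.int(.Machine$integer.max, N)
  K <- gridSize(grid)
  C <- 2L + 2L * nFlankPerSide
  feats <- array(NA_real_, dim = c(N, K, C))
  traj <- matrix(0, N, K)
  labels <- data.frame(class = integer(N), mode = character(N), s = numeric(N),
                       f = numeric(N), onset = numeric(N), nDerived = integer(N),
                       stringsAsFactors = FALSE)
  isSweep <- c(rep(FALSE, nNeutral), rep(TRUE, nSweep))
  for (i in seq_len(N)) {
    set.seed(childSeeds[i])
    rec <- NULL
    for (try in seq_len(maxRetries)) {
      rec <- tryCatch({
        if (isSweep[i]) {
          p <- samplePriors(prior)
          reg <- simulateRegion(p, demography, L = L, n = n)
          site <- reg@focalSite
          tr <- discretizeTrajectory(reg@trajectory, grid)
          onset <- if (p@mode == "soft") {
            fr <- reg@trajectory@freqs
            below <- which(fr < p@fInit)
            if (length(below)) below[1] - 1 else reg@trajectory@originGeneration
          } else reg@trajectory@originGeneration
          list(reg = reg, site = site, traj = tr, p = p, onset = onset)
        } else {
          p <- sweepParams("neutral",
                           mu = stats::runif(1, prior$muRange[1], prior$muRange[2]),
                           rho = stats::runif(1, prior$rhoRange[1], prior$rhoRange[2]))
          target <- stats::runif(1, prior$fRange[1], prior$fRange[2])
          reg <- simulateRegion(p, demography, L = L, n = n)
          site <- pickNeutralFocalSite(reg, target, tolerance = dafTolerance)
          list(reg = reg, site = site, traj = rep(0, K), p = p, onset = 0)
        }
      }, error = function(e) NULL)
      if (!is.null(rec)) break
    }
    if (is.null(rec))
      stop(sprintf("record %d failed after %d retries", i, maxRetries))
    fv <- regionFeatures(rec$reg, grid, site = rec$site,
                         nFlankPerSide = nFlankPerSide)
    feats[i, , ] <- featureValues(fv)
    traj[i, ] <- rec$traj
    labels$class[i] <- as.integer(isSweep[i])
    labels$mode[i] <- rec$p@mode
    labels$s[i] <- rec$p@s
    labels$f[i] <- if (isSweep[i]) rec$p@f else daf(rec$site)
    labels$onset[i] <- rec$onset
    labels$nDerived[i] <- length(rec$site@carriers)
    if (verbose && i %% 200 == 0)
      message(sprintf("  record %d / %d", i, N))
  }
  structure(list(
    features = feats, labels = labels, trajectories = traj,
    meta = list(grid = list(K = K, tMax = grid@tMax, curvature = grid@curvature),
                channels = fvChannelNames(nFlankPerSide),
                normalized = TRUE, n = n, L = L,
                demography = demography@name, prior = unclass(prior),
                masterSeed = seed, childSeeds = childSeeds,
                created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
    class = "sweepDataset")
}

fvChannelNames <- function(nFlankPerSide) {
  c(if (nFlankPerSide > 0L) paste0("left", seq(nFlankPerSide, 1L), "_total"),
    "focal_anc", "focal_der",
    if (nFlankPerSide > 0L) paste0("right", seq_len(nFlankPerSide), "_total"))
}

#' @export
print.sweepDataset <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("sweepDataset: %d records (%d sweep / %d neutral), %d timepoints x %d channels\n",
              d[1], sum(x$labels$class == 1L), sum(x$labels$class == 0L),
              d[2], d[3]))
  invisible(x)
}

#' Write / read a dataset container
#'
#' The container is a directory holding the arrays (\code{payload.rds}) and a
#' human-readable \code{metadata.json} sidecar with the grid parameters,
#' channel order, normalization flag, priors and seeds, so a container is
#' self-describing.
#'
#' @param dataset a \code{sweepDataset}.
#' @param path directory to create.
#' @export
writeDataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset[c("features", "labels", "trajectories")],
          file.path(path, "payload.rds"))
  jsonlite::write_json(dataset$meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeDataset
#' @param path container directory.
#' @export
readDataset <- function(path) {
  payload <- readRDS(file.path(path, "payload.rds"))
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  structure(c(payload, list(meta = meta)), class = "sweepDataset")
}
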