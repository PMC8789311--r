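#' Construct sweep parameters
#'
#' @param mode \code{"neutral"}, \code{"hard"} (sweep from a new mutation) or
#'   \code{"soft"} (partial sweep from standing variation).
#' @param s selection coefficient per generation.
#' @param f present-day segregating frequency of the focal allele.
#' @param fInit frequency at which selection began (soft mode).
#' @param mu per-bp per-generation mutation rate.
#' @param rho per-bp per-generation recombination rate.
#' @return a [SweepParams-class].
#' @export
sweepParams <- function(mode = c("neutral", "hard", "soft"), s = 0, f = 0.5,
                        fInit = NA_real_, mu = 1.25e-8, rho = 1.25e-8) {
  mode <- match.arg(mode)
  new("SweepParams", mode = mode, s = as.numeric(s), f = as.numeric(f),
      fInit = as.numeric(fInit), mu = as.numeric(mu), rho = as.numeric(rho))
}

setMethod("show", "SweepParams", function(object) {
  cat(sprintf("SweepParams: mode %s, s = %g, f = %g%s, mu = %g, rho = %g\n",
              object@mode, object@s, object@f,
              if (object@mode == "soft") sprintf(", fInit = %g", object@fInit) else "",
              object@mu, object@rho))
})

#' Prior specification for simulated training data
#'
#' Uniform priors over the selection and mutation parameters of one simulated
#' region. The defaults reproduce the CEU-like training conditions:
#' s ~ U(1e-4, 0.02), f ~ U(0.01, 0.99), mu and rho ~ U(1.25e-8, 2.5e-8).
#' The capuchino-like configuration uses s ~ U(0.001, 0.02),
#' f ~ U(0.25, 0.99) and fInit ~ U(0.01, 0.05) with soft mode.
#'
#' @param sRange,fRange,muRange,rhoRange numeric length-2 uniform ranges.
#' @param fInitRange range of the soft-sweep standing frequency, used when
#'   \code{mode = "soft"}.
#' @param mode sweep mode drawn regions will carry.
#' @return a list of class \code{"priorSpec"}.
#' @export
priorSpec <- function(sRange = c(1e-4, 0.02), fRange = c(0.01, 0.99),
                      muRange = c(1.25e-8, 2.5e-8), rhoRange = c(1.25e-8, 2.5e-8),
                      fInitRange = c(0.01, 0.05), mode = "hard") {
  chk <- function(r, nm, lower = -Inf) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < lower)
      stop(sprintf("invalid range for %s", nm))
  }
  chk(sRange, "s", 0); chk(fRange, "f", 0); chk(muRange, "mu", 0)
  chk(rhoRange, "rho", 0); chk(fInitRange, "fInit", 0)
  structure(list(sRange = sRange, fRange = fRange, muRange = muRange,
                 rhoRange = rhoRange, fInitRange = fInitRange, mode = mode),
            class = "priorSpec")
}

#' @rdname priorSpec
#' @export
priorSpecCapuchino <- function() {
  priorSpec(sRange = c(0.001, 0.02), fRange = c(0.25, 0.99),
            muRange = c(1e-9, 1e-9), rhoRange = c(1e-9, 1e-9),
            fInitRange = c(0.01, 0.05), mode = "soft")
}

#' Draw sweep parameters from a prior specification
#'
#' Each parameter is drawn independently from its configured uniform range;
#' reproducible under \code{set.seed}.
#'
#' @param spec a [priorSpec()].
#' @return a [SweepParams-class].
#' @export
samplePriors <- function(spec) {
  stopifnot(inherits(spec, "priorSpec"))
  r <- function(rg) if (rg[1] == rg[2]) rg[1] else stats::runif(1, rg[1], rg[2])
  f <- r(spec$fRange)
  fInit <- NA_real_
  if (spec$mode == "soft") {
    fInit <- r(spec$fInitRange)
    if (fInit >= f) fInit <- f / 2          # keep 0 < fInit < f
  }
  sweepParams(mode = spec$mode, s = r(spec$sRange), f = f, fInit = fInit,
              mu = r(spec$muRange), rho = r(spec$rhoRange))
}

.epochMatrix <- function(demography) {
  as.matrix(demography@epochs[, c("start", "size", "growth")])
}

#' Simulate the allele-frequency trajectory of the focal allele
#'
#' Runs a backward-in-time per-generation Wright-Fisher frequency process
#' started at the present-day frequency \code{f}, with genic selection of
#' strength s acting between the present and (soft mode) the first backward
#' crossing of \code{fInit}, conditioned by rejection on a single-copy origin.
#'
#' @param params a [SweepParams-class].
#' @param demography a [DemographyModel-class].
#' @param maxGenerations cap on trajectory length before rejection.
#' @param maxTries rejection-sampling retry cap (default 1000).
#' @return a [Trajectory-class].
#' @export
simulateTrajectory <- function(params, demography = demographyConstant(),
                               maxGenerations = 2e6, maxTries = 1000L) {
  mode <- switch(params@mode, neutral = 0L, hard = 1L, soft = 2L)
  res <- sim_trajectory_cpp(params@s, params@f,
                            if (is.na(params@fInit)) -1 else params@fInit,
                            mode, .epochMatrix(demography),
                            maxGenerations, as.integer(maxTries))
  new("Trajectory", freqs = res$freqs, originGeneration = res$origin)
}

#' @describeIn simulateTrajectory the per-generation frequencies, present first.
#' @param traj a [Trajectory-class].
#' @export
trajectoryFreqs <- function(traj) traj@freqs

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: present-day frequency %.4f, origin %g generations ago\n",
              object@freqs[1], object@originGeneration))
})

#' Simulate a genomic region with local genealogies and haplotypes
#'
#' Simulates the ancestry of \code{n} haplotypes along \code{[0, L)} with a
#' structured coalescent with recombination. For sweep modes, a conditioned
#' allele-frequency trajectory is drawn first (or supplied), lineages at the
#' focal site (placed at L/2) are partitioned into derived/ancestral classes
#' whose coalescence rates follow the trajectory, and all derived lineages
#' merge at the allele's origin. Neutral mode runs the ordinary coalescent
#' with recombination. Mutations are dropped on every local tree under the
#' infinite-sites model; the focal site column is added at L/2 for sweep
#' regions with the derived-class leaves as carriers.
#'
#' @param params a [SweepParams-class].
#' @param demography a [DemographyModel-class].
#' @param L region length in bp (default 1e5).
#' @param n number of sampled haplotypes (default 198, CEU-like panel size;
#'   56 matches the capuchino-like panel; 32 the reduced benchmark).
#' @param trajectory optional pre-computed [Trajectory-class].
#' @param maxGenerations safety cap on the simulated history.
#' @return a [SimulatedRegion-class].
#' @export
simulateRegion <- function(params, demography = demographyConstant(),
                           L = 1e5, n = 198L, trajectory = NULL,
                           maxGenerations = 1e9) {
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 haplotypes")
  if (L <= 0) stop("region length must be positive")
  focal <- L / 2
  if (params@mode == "neutral") {
    traj <- numeric(0)
    trajectory <- NULL
    nDer <- 0L
  } else {
    if (is.null(trajectory))
      trajectory <- simulateTrajectory(params, demography)
    traj <- trajectory@freqs
    # present-day derived count: one binomial sampling step from f
    nDer <- stats::rbinom(1, n, params@f)
    tries <- 0
    while ((nDer < 1L || nDer >= n) && tries < 100) {
      nDer <- stats::rbinom(1, n, params@f)
      tries <- tries + 1
    }
    if (nDer < 1L || nDer >= n)
      nDer <- max(1L, min(n - 1L, as.integer(round(params@f * n))))
  }
  raw <- sim_region_cpp(n, as.integer(nDer), L, params@rho, params@mu,
                        traj, .epochMatrix(demography), focal, maxGenerations)
  trees <- lapply(raw$trees, function(tr)
    localTree(tr$parent, tr$times, interval = c(tr$left, tr$right)))
  haplo <- raw$haplotypes
  pos <- raw$positions
  focalSite <- NULL
  if (params@mode != "neutral") {
    # insert the selected site at L/2 (its carriers are the derived leaves)
    col <- integer(n)
    col[seq_len(nDer)] <- 1L
    at <- findInterval(focal, pos)
    haplo <- cbind(haplo[, seq_len(at), drop = FALSE], col,
                   haplo[, seq_len(ncol(haplo)) > at, drop = FALSE])
    pos <- c(pos[seq_len(at)], focal, pos[seq_len(length(pos)) > at])
    focalSite <- siteLabel(focal, seq_len(nDer), n = n)
  }
  dimnames(haplo) <- NULL
  new("SimulatedRegion", haplotypes = haplo, positions = as.numeric(pos),
      trees = trees, focalSite = focalSite, params = params,
      trajectory = trajectory, L = L, demography = demography@name)
}

setMethod("show", "SimulatedRegion", function(object) {
  cat(sprintf("SimulatedRegion: %d haplotypes, %d sites, %d local trees over [0, %g) (%s, %s)\n",
              nrow(object@haplotypes), ncol(object@haplotypes),
              length(object@trees), object@L, object@params@mode,
              object@demography))
})

#' @describeIn simulateRegion list of local genealogies of a region.
#' @param region a [SimulatedRegion-class].
#' @export
regionTrees <- function(region) region@trees

#' @describeIn simulateRegion the haplotype matrix of a region.
#' @export
regionHaplotypes <- function(region) region@haplotypes

#' @describeIn simulateRegion index of the local tree containing a position.
#' @param position bp coordinate.
#' @export
treeIndexAt <- function(region, position) {
  iv <- vapply(region@trees, function(tr) tr@interval[1], numeric(1))
  findInterval(position, iv)
}

#' Pick a DAF-matched focal site in a neutral region
#'
#' Uniformly selects one segregating site whose derived allele frequency is
#' within \code{tolerance} of \code{targetDaf}. Neutral training features are
#' extracted at such sites so that the classifier cannot separate classes on
#' allele frequency alone.
#'
#' @param region a neutral-mode [SimulatedRegion-class].
#' @param targetDaf target derived allele frequency.
#' @param tolerance admissible |DAF - target| (default 0.02).
#' @return a [SiteLabel-class].
#' @export
pickNeutralFocalSite <- function(region, targetDaf, tolerance = 0.02) {
  if (region@params@mode != "neutral")
    stop("DAF-matched focal sites are drawn from neutral regions")
  n <- nrow(region@haplotypes)
  dafs <- colSums(region@haplotypes) / n
  ok <- which(abs(dafs - targetDaf) <= tolerance & dafs > 0 & dafs < 1)
  if (!length(ok))
    stop(sprintf("no segregating site with DAF within %.3g of %.3g; resimulate",
                 tolerance, targetDaf))
  j <- if (length(ok) == 1L) ok else sample(ok, 1L)
  siteLabel(region@positions[j], which(region@haplotypes[, j] == 1L), n = n)
}

#' Discretize a trajectory onto a time grid
#'
#' Label j is the allele frequency at the nearest generation to grid point j;
#' grid times older than the allele's origin carry label 0 (the allele did
#' not exist yet).
#'
#' @param traj a [Trajectory-class].
#' @param grid a [TimeGrid-class].
#' @return numeric vector of K allele-frequency labels.
#' @export
discretizeTrajectory <- function(traj, grid) {
  pts <- round(gridPoints(grid))
  out <- numeric(length(pts))
  idx <- pts + 1
  inside <- idx <= length(traj@freqs)
  out[inside] <- traj@freqs[idx[inside]]
  out
}
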