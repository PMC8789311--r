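#' @import methods
NULL

#' TimeGrid: discretized time points for genealogy encoding
#'
#' An ordered grid of times (in generations before present) on which every
#' local genealogy is encoded as lineage counts. The grid is approximately
#' log-uniform: spacing between consecutive points is non-decreasing with
#' index, so recent history -- where sweep signal concentrates -- is resolved
#' most finely.
#'
#' @slot points numeric vector of strictly increasing times; \code{points[1] = 0}
#'   and \code{points[K] = tMax}.
#' @slot tMax oldest grid time, generations.
#' @slot curvature positive density parameter; larger values concentrate more
#'   points near the present.
#'
#' @seealso [buildTimeGrid()]
#' @exportClass TimeGrid
setClass("TimeGrid",
  representation(points = "numeric", tMax = "numeric", curvature = "numeric"))

setValidity("TimeGrid", function(object) {
  p <- object@points
  if (length(p) < 2L) return("a TimeGrid needs at least 2 points")
  if (any(!is.finite(p))) return("grid points must be finite")
  if (p[1] != 0) return("first grid point must be 0")
  if (abs(p[length(p)] - object@tMax) > 1e-8 * max(1, object@tMax))
    return("last grid point must equal tMax")
  d <- diff(p)
  if (any(d <= 0)) return("grid points must be strictly increasing")
  if (any(diff(d) < -1e-9 * max(d)))
    return("inter-point spacing must be non-decreasing (finer discretization of recent times)")
  TRUE
})

#' LocalTree: a rooted, timed genealogy over one genomic interval
#'
#' A binary genealogy of \code{n} sampled haplotypes covering the half-open
#' genomic interval \code{[start, end)}. Nodes are stored leaves-first: nodes
#' \code{1..n} are leaves, nodes \code{n+1..2n-1} are internal. \code{parent[i]}
#' gives the parent node of node \code{i} (\code{0} for the root) and
#' \code{times[i]} its time in generations before present (leaves default 0).
#'
#' @slot parent integer vector, length \code{2n - 1}; parent pointers, root = 0.
#' @slot times numeric node times in generations; every internal node is
#'   strictly older than each of its children.
#' @slot labels character leaf labels (length \code{n}).
#' @slot interval numeric length-2 genomic span \code{[start, end)} in bp.
#' @slot branchMap list; optional explicit site-to-branch mapping, named by
#'   position (as character), value = node id below the mutation branch. Takes
#'   precedence over carrier-set matching in [mapMutationBranch()].
#'
#' @seealso [localTree()], [localTreeFromPhylo()], [countLineages()]
#' @exportClass LocalTree
setClass("LocalTree",
  representation(parent = "integer", times = "numeric",
                 labels = "character", interval = "numeric",
                 branchMap = "list"),
  prototype(branchMap = list()))

setValidity("LocalTree", function(object) {
  m <- length(object@parent)
  n <- length(object@labels)
  if (n < 2L) return("need at least 2 leaves")
  if (m != 2L * n - 1L) return("a binary tree over n leaves has 2n - 1 nodes")
  if (length(object@times) != m) return("times must have one entry per node")
  if (sum(object@parent == 0L) != 1L) return("exactly one root (parent 0)")
  kid <- tabulate(object@parent[object@parent > 0L], nbins = m)
  if (any(kid[seq_len(n)] != 0L)) return("leaves cannot have children")
  if (any(kid[(n + 1L):m] != 2L)) return("every internal node must have exactly 2 children")
  has.par <- object@parent > 0L
  if (any(object@times[object@parent[has.par]] <= object@times[has.par]))
    return("every internal node must be strictly older than its children")
  if (length(object@interval) != 2L || object@interval[1] >= object@interval[2])
    return("interval must satisfy start < end")
  TRUE
})

#' SiteLabel: a polymorphic site and its derived-allele carriers
#'
#' @slot position bp coordinate of the site.
#' @slot carriers integer indices (leaf numbers) of haplotypes carrying the
#'   derived allele; must be a proper non-empty subset of the sample.
#' @slot n sample size (number of haplotypes).
#'
#' @exportClass SiteLabel
setClass("SiteLabel",
  representation(position = "numeric", carriers = "integer", n = "integer"))

setValidity("SiteLabel", function(object) {
  k <- length(object@carriers)
  if (object@n < 2L) return("sample size must be >= 2")
  if (k == 0L || k >= object@n)
    return("site must be polymorphic: 0 < |carriers| < n")
  if (any(object@carriers < 1L | object@carriers > object@n))
    return("carrier indices out of range")
  if (anyDuplicated(object@carriers)) return("duplicate carrier indices")
  TRUE
})

#' FeatureVector: lineage-count encoding of a focal site with flanking trees
#'
#' The fixed-dimension genealogical feature of one focal site: a K-timepoint
#' by C-channel matrix. With the default two flanking trees per side the
#' channels are, in order: left-2 total, left-1 total, focal ancestral,
#' focal derived, right-1 total, right-2 total -- a 600-dimensional feature
#' with the default 100-point grid. Row 1 is the present; rows advance into
#' the past.
#'
#' @slot values numeric K x C matrix of (optionally normalized) lineage counts.
#' @slot channels character vector naming the C channels.
#' @slot normalized logical; TRUE if counts were divided by the sample size.
#' @slot n integer sample size used for normalization.
#'
#' @seealso [extractFeatures()], [shapeInput()]
#' @exportClass FeatureVector
setClass("FeatureVector",
  representation(values = "matrix", channels = "character",
                 normalized = "logical", n = "integer"))

setValidity("FeatureVector", function(object) {
  if (ncol(object@values) != length(object@channels))
    return("one channel name per column")
  if (object@normalized && any(object@values > 1 + 1e-9))
    return("normalized counts must lie in (0, 1]")
  TRUE
})

#' SweepParams: selection/mutation parameters of one simulated region
#'
#' @slot mode one of \code{"neutral"}, \code{"hard"}, \code{"soft"}.
#' @slot s selection coefficient per generation (>= 0).
#' @slot f present-day segregating frequency of the selected allele.
#' @slot fInit frequency at which selection began acting (soft mode only;
#'   \code{NA} otherwise).
#' @slot mu per-bp per-generation mutation rate.
#' @slot rho per-bp per-generation recombination rate.
#'
#' @seealso [sweepParams()], [samplePriors()]
#' @exportClass SweepParams
setClass("SweepParams",
  representation(mode = "character", s = "numeric", f = "numeric",
                 fInit = "numeric", mu = "numeric", rho = "numeric"))

setValidity("SweepParams", function(object) {
  if (!object@mode %in% c("neutral", "hard", "soft")) return("unknown mode")
  if (object@s < 0) return("s must be >= 0")
  if (object@f <= 0 || object@f >= 1) return("f must lie in (0, 1)")
  if (object@mode == "soft" &&
      (is.na(object@fInit) || object@fInit <= 0 || object@fInit >= object@f))
    return("soft mode needs 0 < fInit < f")
  if (object@mu <= 0 || object@rho < 0) return("mu must be > 0 and rho >= 0")
  TRUE
})

#' DemographyModel: piecewise population-size history
#'
#' Epochs are ordered from the present backwards; epoch \code{i} starts at
#' \code{start[i]} generations before present with diploid size \code{size[i]}
#' and (forward-time) exponential growth rate \code{growth[i]}, so within an
#' epoch \code{N(t) = size * exp(-growth * (t - start))}.
#'
#' @slot epochs data.frame with columns \code{start}, \code{size}, \code{growth}.
#' @slot name model identifier.
#'
#' @seealso [demographyModel()], [demographyConstant()], [demographyCEU()],
#'   [demographyCapuchino()]
#' @exportClass DemographyModel
setClass("DemographyModel",
  representation(epochs = "data.frame", name = "character"))

setValidity("DemographyModel", function(object) {
  e <- object@epochs
  if (!all(c("start", "size", "growth") %in% names(e)))
    return("epochs need columns start, size, growth")
  if (nrow(e) < 1L) return("need at least one epoch")
  if (e$start[1] != 0) return("first epoch must start at 0")
  if (is.unsorted(e$start, strictly = TRUE)) return("epoch starts must be strictly increasing")
  if (any(e$size <= 0)) return("population sizes must be > 0")
  TRUE
})

#' Trajectory: per-generation allele-frequency history of the focal allele
#'
#' \code{freqs[1]} is the present-day frequency; index g + 1 is the frequency
#' g generations before present; the final entry corresponds to the single
#' founding copy at the allele's origin.
#'
#' @slot freqs numeric frequencies in [0, 1], present first.
#' @slot originGeneration age of the allele in generations.
#'
#' @seealso [simulateTrajectory()], [discretizeTrajectory()]
#' @exportClass Trajectory
setClass("Trajectory",
  representation(freqs = "numeric", originGeneration = "numeric"))

setValidity("Trajectory", function(object) {
  f <- object@freqs
  if (length(f) < 1L) return("empty trajectory")
  if (any(f < 0 | f > 1)) return("frequencies must lie in [0, 1]")
  if (object@originGeneration != length(f) - 1L)
    return("originGeneration must equal length(freqs) - 1")
  TRUE
})

#' SimulatedRegion: one simulated genomic region with truth labels
#'
#' @slot haplotypes n x S binary matrix (0 ancestral, 1 derived allele).
#' @slot positions bp coordinates of the S variant columns, ascending.
#' @slot trees list of [LocalTree-class] tiling \code{[0, L)} without gaps.
#' @slot focalSite [SiteLabel-class] of the selected site (sweep regions) or
#'   the DAF-matched neutral focal site; may be \code{NULL} before selection.
#' @slot params [SweepParams-class] truth parameters.
#' @slot trajectory [Trajectory-class] truth trajectory (sweep modes) or
#'   \code{NULL}.
#' @slot L region length, bp.
#' @slot demography name of the demographic model used.
#'
#' @seealso [simulateRegion()]
#' @exportClass SimulatedRegion
setClass("SimulatedRegion",
  representation(haplotypes = "matrix", positions = "numeric", trees = "list",
                 focalSite = "ANY", params = "SweepParams", trajectory = "ANY",
                 L = "numeric", demography = "character"))

setValidity("SimulatedRegion", function(object) {
  if (length(object@positions) != ncol(object@haplotypes))
    return("one position per haplotype column")
  if (is.unsorted(object@positions)) return("positions must be ascending")
  if (length(object@trees) < 1L) return("need at least one local tree")
  iv <- t(vapply(object@trees, function(tr) tr@interval, numeric(2)))
  if (abs(iv[1, 1]) > 1e-9 || abs(iv[nrow(iv), 2] - object@L) > 1e-6)
    return("trees must cover [0, L)")
  if (nrow(iv) > 1L && any(abs(iv[-1, 1] - iv[-nrow(iv), 2]) > 1e-6))
    return("tree intervals must tile without gaps or overlaps")
  TRUE
})

#' SweepModel: a trained stacked-LSTM selection-inference model
#'
#' @slot weights list of parameter matrices per LSTM stack plus output head.
#' @slot config list; the [netConfig()] the model was trained with.
#' @slot task character; one of classify, regress_s, regress_onset, trajectory.
#' @slot log data.frame of per-epoch training and validation loss.
#' @slot meta list; grid parameters, channel order, normalization flag and
#'   target scaling, making a checkpoint self-describing.
#'
#' @seealso [trainModel()], [saveModel()], [loadModel()]
#' @exportClass SweepModel
setClass("SweepModel",
  representation(weights = "list", config = "list", task = "character",
                 log = "data.frame", meta = "list"))

#' Prediction: model output for one focal site
#'
#' @slot task the model task that produced the prediction.
#' @slot point numeric point estimate: sweep probability, s-hat, onset-hat, or
#'   (trajectory task) the K per-timepoint allele frequencies.
#' @slot samples numeric Monte Carlo dropout samples backing the interval
#'   (matrix for trajectories), or length 0 for plain predictions.
#' @slot ci numeric length-2 percentile interval (matrix 2 x K for trajectories),
#'   or length 0.
#' @slot level interval coverage level.
#'
#' @seealso [predictWithDropout()]
#' @exportClass Prediction
setClass("Prediction",
  representation(task = "character", point = "numeric", samples = "ANY",
                 ci = "ANY", level = "numeric"))
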