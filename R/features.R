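#' Extract the lineage-count feature vector for a focal site
#'
#' Encodes the focal genealogy as ancestral/derived lineage counts on the time
#' grid, and each of the \code{nFlankPerSide} nearest distinct genealogies on
#' either side as total lineage counts, concatenated in the fixed channel
#' order left-outermost .. left-1, focal-ancestral, focal-derived, right-1 ..
#' right-outermost. With the defaults (K = 100 grid points, two flanking trees
#' per side) the feature has 6 channels and 600 values. At contig edges,
#' missing flanks are filled by repeating the outermost available tree. Counts
#' are divided by the sample size n when \code{normalize = TRUE} so that
#' features transfer across data sets of the same n.
#'
#' @param trees list of [LocalTree-class], ordered by genomic interval.
#' @param focalIndex index into \code{trees} of the genealogy containing the
#'   focal site.
#' @param site focal [SiteLabel-class]; its position must fall in the focal
#'   tree's interval.
#' @param grid a [TimeGrid-class].
#' @param nFlankPerSide number of flanking genealogies per side (default 2).
#' @param normalize divide counts by n (default TRUE).
#' @param bestMatch passed to [mapMutationBranch()].
#' @return a [FeatureVector-class] with K x (2 + 2 nFlankPerSide) values.
#' @export
extractFeatures <- function(trees, focalIndex, site, grid,
                            nFlankPerSide = 2L, normalize = TRUE,
                            bestMatch = FALSE) {
  nFlankPerSide <- as.integer(nFlankPerSide)
  if (nFlankPerSide < 0L) stop("nFlankPerSide must be >= 0")
  focal <- trees[[focalIndex]]
  iv <- focal@interval
  if (site@position < iv[1] || site@position >= iv[2])
    stop(sprintf("focal site %.6g lies outside the focal tree interval [%.6g, %.6g)",
                 site@position, iv[1], iv[2]))
  K <- gridSize(grid)
  n <- nLeaves(focal)

  flankIdx <- function(offsets) {
    # clamp at contig edges: repeat the outermost available tree
    pmin(pmax(focalIndex + offsets, 1L), length(trees))
  }
  leftIdx  <- if (nFlankPerSide > 0L) flankIdx(seq(-nFlankPerSide, -1L)) else integer(0)
  rightIdx <- if (nFlankPerSide > 0L) flankIdx(seq(1L, nFlankPerSide)) else integer(0)

  foc <- encodeFocal(focal, site, grid, bestMatch = bestMatch)
  cols <- c(lapply(leftIdx, function(i) encodeFlank(trees[[i]], grid)),
            list(foc[, "anc"], foc[, "der"]),
            lapply(rightIdx, function(i) encodeFlank(trees[[i]], grid)))
  vals <- do.call(cbind, cols)
  chn <- c(if (nFlankPerSide > 0L) paste0("left", seq(nFlankPerSide, 1L), "_total"),
           "focal_anc", "focal_der",
           if (nFlankPerSide > 0L) paste0("right", seq_len(nFlankPerSide), "_total"))
  colnames(vals) <- chn
  if (normalize) vals <- vals / n
  new("FeatureVector", values = vals, channels = chn,
      normalized = normalize, n = as.integer(n))
}

#' Reshape a feature vector for the recurrent model
#'
#' Returns the K x C matrix fed to the LSTM one timestep (row) at a time,
#' present first. Accepts a [FeatureVector-class] or a bare numeric vector of
#' length K * C (column-major by channel, matching \code{featureValues}).
#'
#' @param fv a [FeatureVector-class] or numeric vector.
#' @param K number of timesteps, required for bare vectors.
#' @return numeric K x C matrix.
#' @export
shapeInput <- function(fv, K = 100L) {
  if (is(fv, "FeatureVector")) return(fv@values)
  fv <- as.numeric(fv)
  if (length(fv) %% K != 0L)
    stop(sprintf("feature length %d is not divisible by K = %d", length(fv), K))
  matrix(fv, nrow = K)
}

#' @describeIn extractFeatures the K x C value matrix of a feature vector.
#' @param fv a [FeatureVector-class].
#' @export
featureValues <- function(fv) fv@values

#' @describeIn extractFeatures flatten a feature vector to length K * C
#'   (column-major, the documented channel order).
#' @export
featureFlatten <- function(fv) as.numeric(fv@values)

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector: %d timepoints x %d channels (%s, n = %d)\n",
              nrow(object@values), ncol(object@values),
              if (object@normalized) "normalized" else "raw counts", object@n))
  cat(" channels:", paste(object@channels, collapse = ", "), "\n")
})
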