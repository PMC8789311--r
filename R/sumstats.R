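#' Classical diversity statistics of a haplotype block
#'
#' Computes, over the segregating columns of a binary haplotype matrix
#' (rows = haplotypes, 0 ancestral / 1 derived): the number of segregating
#' sites ss; nucleotide diversity pi (mean pairwise differences); Watterson's
#' theta_W = ss / a1 with a1 = sum_{i<n} 1/i; Fay and Wu's
#' theta_H = sum_j 2 c_j^2 / (n (n-1)) over derived counts c_j; Tajima's D
#' with its standard variance normalization (NA when ss = 0); and the number
#' of distinct haplotypes.
#'
#' @param haplo n x S binary matrix.
#' @return named list with ss, pi, thetaW, thetaH, tajimasD, nHaplotypes.
#' @export
basicStats <- function(haplo) {
  n <- nrow(haplo)
  if (n < 2L) stop("need at least 2 haplotypes")
  cnt <- colSums(haplo)
  seg <- cnt > 0 & cnt < n
  c2 <- cnt[seg]
  S <- length(c2)
  npairs <- n * (n - 1) / 2
  pi <- sum(c2 * (n - c2)) / npairs
  a1 <- sum(1 / seq_len(n - 1))
  thetaW <- S / a1
  thetaH <- sum(2 * c2^2) / (n * (n - 1))
  D <- NA_real_
  if (S > 0) {
    a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    cc1 <- b1 - 1 / a1
    cc2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- cc1 / a1
    e2 <- cc2 / (a1^2 + a2)
    v <- e1 * S + e2 * S * (S - 1)
    D <- if (v > 0) (pi - thetaW) / sqrt(v) else NA_real_
  }
  list(ss = S, pi = pi, thetaW = thetaW, thetaH = thetaH, tajimasD = D,
       nHaplotypes = nrow(unique(haplo)))
}

#' Garud's haplotype-homozygosity statistics
#'
#' With sorted haplotype frequencies p1 >= p2 >= ...: H1 = sum p_i^2,
#' H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2 (sensitive to soft sweeps where two
#' haplotypes ride to high frequency), and H2/H1 = (H1 - p1^2) / H1.
#'
#' @param haplo n x S binary matrix.
#' @return named list with H1, H12, H2H1.
#' @export
garudH <- function(haplo) {
  key <- apply(haplo, 1, paste, collapse = "")
  p <- sort(as.numeric(table(key)) / nrow(haplo), decreasing = TRUE)
  H1 <- sum(p^2)
  p2 <- if (length(p) >= 2) p[2] else 0
  H12 <- (p[1] + p2)^2 + if (length(p) >= 3) sum(p[-(1:2)]^2) else 0
  list(H1 = H1, H12 = H12, H2H1 = (H1 - p[1]^2) / H1)
}

# r^2 matrix over segregating columns (squared Pearson correlation of 0/1
# alleles, the standard haplotype-data LD measure)
.r2Matrix <- function(haplo) {
  cnt <- colSums(haplo)
  seg <- cnt > 0 & cnt < nrow(haplo)
  m <- haplo[, seg, drop = FALSE]
  if (ncol(m) < 2) return(NULL)
  suppressWarnings(stats::cor(m))^2
}

#' Average pairwise linkage disequilibrium (ZnS)
#'
#' Mean of r^2 over all pairs of segregating sites in the block; NA with
#' fewer than 2 segregating sites.
#'
#' @param haplo n x S binary matrix.
#' @return numeric scalar.
#' @export
zns <- function(haplo) {
  r2 <- .r2Matrix(haplo)
  if (is.null(r2)) return(NA_real_)
  mean(r2[upper.tri(r2)])
}

#' Maximum omega statistic
#'
#' The Kim-Nielsen omega contrasts linkage disequilibrium within the two
#' blocks either side of a putative sweep target against LD across them:
#' for a split after site l (of S segregating sites),
#' \deqn{\omega_l = \frac{\left(\binom{l}{2} + \binom{S-l}{2}\right)^{-1}
#'   \left(\sum_{i,j \le l} r^2_{ij} + \sum_{i,j > l} r^2_{ij}\right)}
#'   {\frac{1}{l(S-l)} \sum_{i \le l < j} r^2_{ij}}.}
#' All S - 1 splits with at least one site per side are evaluated and the
#' maximum returned; NA with fewer than 3 segregating sites.
#'
#' @param haplo n x S binary matrix.
#' @return numeric scalar.
#' @export
omegaMax <- function(haplo) {
  r2 <- .r2Matrix(haplo)
  if (is.null(r2) || ncol(r2) < 3) return(NA_real_)
  S <- ncol(r2)
  best <- -Inf
  for (l in seq_len(S - 1)) {
    li <- seq_len(l); ri <- (l + 1):S
    wL <- if (l >= 2) sum(r2[li, li][upper.tri(r2[li, li])]) else 0
    wR <- if (length(ri) >= 2) sum(r2[ri, ri][upper.tri(r2[ri, ri])]) else 0
    nw <- choose(l, 2) + choose(S - l, 2)
    xb <- sum(r2[li, ri])
    num <- if (nw > 0) (wL + wR) / nw else 0
    den <- xb / (l * (S - l))
    om <- num / den               # Inf when cross-block LD vanishes entirely
    if (!is.nan(om) && om > best) best <- om
  }
  if (best > -Inf) best else NA_real_
}

# EHH decay away from a core site for one haplotype group; returns the
# EHH-integrated haplotype homozygosity (trapezoid over bp, truncated where
# EHH drops below `trunc`), summed over the two directions.
.ihh <- function(haplo, positions, core, rows, trunc = 0.05) {
  g <- length(rows)
  if (g < 2) return(NA_real_)
  npair <- g * (g - 1) / 2
  oneSide <- function(idx) {
    # idx: site indices walking outward from the core (excluding it)
    ehh <- 1
    x0 <- positions[core]
    integral <- 0
    key <- rep("", g)
    lastE <- 1; lastX <- x0
    for (j in idx) {
      key <- paste0(key, haplo[rows, j])
      tab <- table(key)
      e <- sum(tab * (tab - 1) / 2) / npair
      x <- positions[j]
      integral <- integral + (lastE + e) / 2 * abs(x - lastX)
      lastE <- e; lastX <- x
      if (e < trunc) break
    }
    integral
  }
  right <- if (core < ncol(haplo)) oneSide((core + 1):ncol(haplo)) else 0
  left  <- if (core > 1) oneSide((core - 1):1) else 0
  left + right
}

#' Unstandardized iHS at one core site
#'
#' The log-ratio ln(iHH_A / iHH_D) of the EHH-integrated haplotype
#' homozygosities of the ancestral- and derived-allele carriers at the core,
#' integrating EHH over bp distance by the trapezoid rule and truncating each
#' direction where EHH falls below \code{trunc}.
#'
#' @param haplo n x S binary matrix.
#' @param positions bp coordinates of the S columns.
#' @param core column index of the core site.
#' @param trunc EHH truncation threshold (default 0.05).
#' @return numeric scalar (NA if either allele class has < 2 carriers or a
#'   zero integral).
#' @export
ihsSite <- function(haplo, positions, core, trunc = 0.05) {
  der <- which(haplo[, core] == 1)
  anc <- which(haplo[, core] == 0)
  ihhD <- .ihh(haplo, positions, core, der, trunc)
  ihhA <- .ihh(haplo, positions, core, anc, trunc)
  if (is.na(ihhD) || is.na(ihhA) || ihhD <= 0 || ihhA <= 0) return(NA_real_)
  log(ihhA / ihhD)
}

#' Region-level iHS score
#'
#' Computes unstandardized iHS at every site with minor allele frequency
#' above \code{mafMin}, standardizes the scores to zero mean and unit
#' variance within \code{nBins} equal-width derived-allele-frequency bins
#' (bins with fewer than 2 scored sites fall back to the global
#' standardization), and returns the mean standardized score over all scored
#' sites (plus the per-site table).
#'
#' @param haplo n x S binary matrix.
#' @param positions bp coordinates.
#' @param mafMin minor-AF threshold (default 0.05).
#' @param nBins number of derived-AF standardization bins (default 50).
#' @param trunc EHH truncation threshold.
#' @return list with \code{score} (region mean), and \code{sites}
#'   (data.frame: position, daf, uihs, std).
#' @export
ihsRegion <- function(haplo, positions, mafMin = 0.05, nBins = 50L,
                      trunc = 0.05) {
  n <- nrow(haplo)
  dafs <- colSums(haplo) / n
  use <- which(pmin(dafs, 1 - dafs) > mafMin)
  if (!length(use))
    return(list(score = NA_real_, sites = data.frame()))
  u <- vapply(use, function(j) ihsSite(haplo, positions, j, trunc), numeric(1))
  keep <- is.finite(u)
  use <- use[keep]; u <- u[keep]
  if (!length(use))
    return(list(score = NA_real_, sites = data.frame()))
  bin <- pmin(nBins, pmax(1L, ceiling(dafs[use] * nBins)))
  gm <- mean(u); gs <- stats::sd(u)
  if (!is.finite(gs) || gs == 0) gs <- 1
  std <- numeric(length(u))
  for (b in unique(bin)) {
    i <- which(bin == b)
    if (length(i) >= 2 && stats::sd(u[i]) > 0) {
      std[i] <- (u[i] - mean(u[i])) / stats::sd(u[i])
    } else {
      std[i] <- (u[i] - gm) / gs
    }
  }
  list(score = mean(std),
       sites = data.frame(position = positions[use], daf = dafs[use],
                          uihs = u, std = std))
}

#' Windowed summary-statistic features
#'
#' Computes 11 statistics (ss, pi, theta_W, theta_H, Tajima's D, number of
#' distinct haplotypes, H1, H12, H2/H1, ZnS, omega_max) in five consecutive
#' equal-bp windows of the block, then normalizes each statistic's five
#' values by their row sum -- the feature encoding used by windowed
#' sweep classifiers looking for a signal concentrated in the middle window.
#' Rows whose raw sum is zero (or all-NA) are emitted as all-NA.
#'
#' @param haplo n x S binary matrix spanning the region.
#' @param positions bp coordinates of the columns.
#' @param start,end region bounds in bp (default: 0 to max position).
#' @param nWindows number of windows (default 5).
#' @return list with \code{normalized} and \code{raw} (statistics x windows
#'   matrices).
#' @export
windowFeatures <- function(haplo, positions, start = 0, end = NULL,
                           nWindows = 5L) {
  if (is.null(end)) end <- max(positions) + 1
  edges <- seq(start, end, length.out = nWindows + 1)
  statNames <- c("ss", "pi", "thetaW", "thetaH", "tajimasD", "nHaplotypes",
                 "H1", "H12", "H2H1", "ZnS", "omegaMax")
  raw <- matrix(NA_real_, length(statNames), nWindows,
                dimnames = list(statNames, paste0("w", seq_len(nWindows))))
  for (w in seq_len(nWindows)) {
    j <- which(positions >= edges[w] & positions < edges[w + 1])
    m <- haplo[, j, drop = FALSE]
    bs <- basicStats(m)
    gh <- garudH(m)
    raw[, w] <- c(bs$ss, bs$pi, bs$thetaW, bs$thetaH, bs$tajimasD,
                  bs$nHaplotypes, gh$H1, gh$H12, gh$H2H1, zns(m), omegaMax(m))
  }
  norm <- raw
  for (r in seq_len(nrow(raw))) {
    s <- sum(raw[r, ])
    norm[r, ] <- if (is.finite(s) && s != 0) raw[r, ] / s else NA_real_
  }
  list(normalized = norm, raw = raw)
}

#' Sort haplotypes by Manhattan distance
#'
#' The canonical ordering used before encoding haplotypes as an image:
#' (1) compute all pairwise Manhattan distances; (2) place first the
#' haplotype with the smallest total distance to all others; (3) sort the
#' rest by increasing distance to that first haplotype. All ties break by
#' original row index, so the sort is deterministic.
#'
#' @param haplo n x S binary matrix.
#' @return list with \code{matrix} (permuted rows) and \code{order} (the
#'   permutation applied).
#' @export
haplotypeSort <- function(haplo) {
  d <- as.matrix(stats::dist(haplo, method = "manhattan"))
  first <- unname(which.min(rowSums(d)))           # ties: smallest index
  rest <- setdiff(seq_len(nrow(haplo)), first)
  ord <- as.integer(c(first, rest[order(d[rest, first], rest)]))
  list(matrix = haplo[ord, , drop = FALSE], order = ord)
}

#' Fixed-size genotype image of a region
#'
#' Builds the fixed-dimension image encoding used by genotype-based
#' convolutional classifiers: haplotypes are Manhattan-sorted, then up to
#' \code{halfWidth} variants either side of the focal variant are retained
#' (the focal variant sits at column \code{halfWidth + 1}), and missing
#' variants are zero-padded outward. With a 198-haplotype panel and
#' \code{halfWidth = 180} the image is a 198 x 360 binary matrix.
#'
#' @param haplo n x S binary matrix.
#' @param positions bp coordinates of the columns.
#' @param focalIndex column index of the focal (middle) variant.
#' @param halfWidth variants retained per side (default 180).
#' @return list with \code{image} (n x 2*halfWidth matrix) and
#'   \code{positions} (length 2*halfWidth; padded entries 0).
#' @export
genotypeImage <- function(haplo, positions, focalIndex, halfWidth = 180L) {
  if (focalIndex < 1 || focalIndex > ncol(haplo)) stop("invalid focal index")
  n <- nrow(haplo)
  sorted <- haplotypeSort(haplo)$matrix
  W <- 2L * halfWidth
  img <- matrix(0L, n, W)
  pos <- numeric(W)
  left <- max(1L, focalIndex - halfWidth):max(0L, focalIndex - 1L)
  if (focalIndex == 1L) left <- integer(0)
  right <- if (focalIndex < ncol(haplo))
    (focalIndex + 1L):min(ncol(haplo), focalIndex + halfWidth - 1L) else integer(0)
  # focal at column halfWidth + 1; left block right-aligned against it
  lcols <- (halfWidth + 1L - length(left)):halfWidth
  if (length(left)) {
    img[, lcols] <- sorted[, left]
    pos[lcols] <- positions[left]
  }
  img[, halfWidth + 1L] <- sorted[, focalIndex]
  pos[halfWidth + 1L] <- positions[focalIndex]
  if (length(right)) {
    rcols <- (halfWidth + 2L):(halfWidth + 1L + length(right))
    img[, rcols] <- sorted[, right]
    pos[rcols] <- positions[right]
  }
  list(image = img, positions = pos)
}
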