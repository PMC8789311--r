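#' Construct a LocalTree
#'
#' @param parent integer parent pointers over \code{2n - 1} nodes
#'   (leaves \code{1..n} first, root marked 0).
#' @param times node times in generations before present.
#' @param labels leaf labels; default \code{"h1".."hn"}.
#' @param interval genomic span \code{c(start, end)} in bp.
#' @param branchMap optional named list mapping site positions (as character)
#'   to the node id under the branch carrying their mutation.
#' @return a validated [LocalTree-class].
#' @examples
#' # ((A,B):1, (C,D):2) root at 3
#' tr <- localTree(parent = c(5L, 5L, 6L, 6L, 7L, 7L, 0L),
#'                 times = c(0, 0, 0, 0, 1, 2, 3),
#'                 labels = c("A", "B", "C", "D"), interval = c(0, 100))
#' countLineages(tr, 1.5)  # 3
#' @export
localTree <- function(parent, times, labels = NULL, interval = c(0, 1),
                      branchMap = list()) {
  parent <- as.integer(parent)
  n <- (length(parent) + 1L) %/% 2L
  if (is.null(labels)) labels <- paste0("h", seq_len(n))
  new("LocalTree", parent = parent, times = as.numeric(times),
      labels = as.character(labels), interval = as.numeric(interval),
      branchMap = branchMap)
}

#' @describeIn localTree number of leaves.
#' @param tree a [LocalTree-class].
#' @export
nLeaves <- function(tree) length(tree@labels)

#' @describeIn localTree root node id.
#' @export
rootNode <- function(tree) which(tree@parent == 0L)

#' @describeIn localTree time of the most recent common ancestor of the sample.
#' @export
treeTMRCA <- function(tree) tree@times[which(tree@parent == 0L)]

#' @describeIn localTree genomic interval covered by the tree.
#' @export
treeInterval <- function(tree) tree@interval

setMethod("show", "LocalTree", function(object) {
  cat(sprintf("LocalTree: %d leaves, interval [%.6g, %.6g), TMRCA %.6g generations\n",
              nLeaves(object), object@interval[1], object@interval[2],
              treeTMRCA(object)))
})

#' Construct a SiteLabel
#'
#' @param position bp coordinate of the site.
#' @param carriers derived-allele carriers: integer leaf indices or character
#'   leaf labels (resolved against \code{labels}).
#' @param n sample size, or NULL if \code{labels} given.
#' @param labels optional leaf labels used to resolve character carriers.
#' @return a validated [SiteLabel-class].
#' @export
siteLabel <- function(position, carriers, n = NULL, labels = NULL) {
  if (is.character(carriers)) {
    if (is.null(labels)) stop("character carriers need leaf labels to resolve against")
    idx <- match(carriers, labels)
    if (anyNA(idx)) stop("unknown carrier label(s): ",
                         paste(carriers[is.na(idx)], collapse = ", "))
    carriers <- idx
    if (is.null(n)) n <- length(labels)
  }
  new("SiteLabel", position = as.numeric(position),
      carriers = sort(as.integer(carriers)), n = as.integer(n))
}

#' @describeIn siteLabel derived allele frequency of the site in the sample.
#' @param site a [SiteLabel-class].
#' @export
daf <- function(site) length(site@carriers) / site@n

setMethod("show", "SiteLabel", function(object) {
  cat(sprintf("SiteLabel: position %.6g, %d/%d derived carriers (DAF %.3f)\n",
              object@position, length(object@carriers), object@n, daf(object)))
})

#' Count lineages of a genealogy active at a time point
#'
#' A branch \code{[child_time, parent_time)} is active at time t iff
#' \code{child_time <= t < parent_time} (half-open convention: each
#' coalescence reduces the count exactly once). At and above the root time
#' the count clamps to 1, representing the persisting ancestral lineage.
#'
#' @param tree a [LocalTree-class].
#' @param t time(s) in generations before present (vectorized).
#' @return integer lineage count(s).
#' @export
countLineages <- function(tree, t) {
  stopifnot(all(t >= 0))
  root <- which(tree@parent == 0L)
  ct <- tree@times[tree@parent != 0L]            # child (branch lower) times
  pt <- tree@times[tree@parent[tree@parent != 0L]]  # branch upper times
  out <- vapply(t, function(tt) {
    if (tt >= tree@times[root]) return(1L)
    sum(ct <= tt & tt < pt)
  }, integer(1))
  out
}

# node ids of node and all its descendants
.subtreeNodes <- function(tree, node) {
  m <- length(tree@parent)
  keep <- logical(m)
  keep[node] <- TRUE
  # children lists
  kids <- split(seq_len(m)[tree@parent > 0L], tree@parent[tree@parent > 0L])
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) {
      keep[ch] <- TRUE
      stack <- c(stack, ch)
    }
  }
  which(keep)
}

# leaf indices under node
.leafSet <- function(tree, node) {
  n <- nLeaves(tree)
  sub <- .subtreeNodes(tree, node)
  sort(sub[sub <= n])
}

#' Map a polymorphic site to the branch carrying its mutation
#'
#' Under the infinite-sites assumption (biallelic, no recurrent mutation) the
#' derived allele traces to a single mutation on the unique branch whose
#' subtended leaves are exactly the carrier set. The branch is identified by
#' the node at its lower end. An explicit \code{branchMap} entry on the tree
#' takes precedence. When an inferred tree is incompatible with the carrier
#' set, \code{bestMatch = TRUE} instead returns the branch maximizing the
#' Jaccard similarity between its leaf set and the carriers (ties broken by
#' the smaller node id).
#'
#' @param tree a [LocalTree-class].
#' @param site a [SiteLabel-class].
#' @param bestMatch logical; enable the maximal-Jaccard fallback (default
#'   FALSE: incompatibility is an error).
#' @return integer node id below the mutation branch.
#' @export
mapMutationBranch <- function(tree, site, bestMatch = FALSE) {
  n <- nLeaves(tree)
  k <- length(site@carriers)
  if (k == 0L || k >= n)
    stop("monomorphic site: carriers must be a proper non-empty subset of the sample")
  key <- as.character(site@position)
  if (length(tree@branchMap) && !is.null(tree@branchMap[[key]]))
    return(as.integer(tree@branchMap[[key]]))
  if (k == 1L) return(site@carriers)        # leaf branch
  m <- length(tree@parent)
  car <- site@carriers
  best <- 0L; bestJ <- -1
  for (v in (n + 1L):m) {
    if (tree@parent[v] == 0L) next          # branch above root does not exist
    ls <- .leafSet(tree, v)
    if (length(ls) == k && all(ls == car)) return(v)
    if (bestMatch) {
      j <- length(intersect(ls, car)) / length(union(ls, car))
      if (j > bestJ) { bestJ <- j; best <- v }
    }
  }
  if (bestMatch) {
    # also consider leaf branches
    for (v in seq_len(n)) {
      j <- as.numeric(v %in% car) / (k + 1L - as.numeric(v %in% car))
      if (j > bestJ) { bestJ <- j; best <- v }
    }
    return(best)
  }
  stop("carrier set is incompatible with the tree: no branch subtends exactly these leaves")
}

#' Count ancestral and derived lineages at a time point
#'
#' Splits the active lineages of the focal genealogy at time t into those on
#' the derived background (the mutation branch and its descendants) and the
#' rest. At and above the upper end of the mutation branch all lineages are
#' ancestral.
#'
#' @inheritParams mapMutationBranch
#' @param t time in generations before present (vectorized).
#' @return integer matrix with columns \code{anc}, \code{der}; one row per t.
#' @export
classifyLineages <- function(tree, site, t, bestMatch = FALSE) {
  mnode <- mapMutationBranch(tree, site, bestMatch = bestMatch)
  sub <- .subtreeNodes(tree, mnode)
  isDer <- logical(length(tree@parent))
  isDer[sub] <- TRUE
  root <- which(tree@parent == 0L)
  branch <- which(tree@parent != 0L)
  ct <- tree@times[branch]
  pt <- tree@times[tree@parent[branch]]
  der <- vapply(t, function(tt) {
    if (tt >= tree@times[root]) return(0L)
    sum(isDer[branch] & ct <= tt & tt < pt)
  }, integer(1))
  tot <- countLineages(tree, t)
  cbind(anc = tot - der, der = der)
}

#' Encode the focal genealogy on a time grid
#'
#' @param tree focal [LocalTree-class].
#' @param site focal [SiteLabel-class].
#' @param grid a [TimeGrid-class].
#' @param bestMatch passed to [mapMutationBranch()].
#' @return integer matrix K x 2 with columns \code{anc}, \code{der}.
#' @export
encodeFocal <- function(tree, site, grid, bestMatch = FALSE) {
  classifyLineages(tree, site, gridPoints(grid), bestMatch = bestMatch)
}

#' Encode a flanking genealogy on a time grid
#'
#' @param tree a [LocalTree-class].
#' @param grid a [TimeGrid-class].
#' @return integer vector of K total lineage counts.
#' @export
encodeFlank <- function(tree, grid) {
  countLineages(tree, gridPoints(grid))
}

#' Convert an ape phylo to a LocalTree
#'
#' Branch lengths must be in generations. Node times are taken as distance
#' below the highest tip (tips of an ultrametric tree sit at time 0).
#'
#' @param phy an [ape::phylo] object (rooted, binary, with edge lengths).
#' @param interval genomic span \code{c(start, end)} covered by the tree.
#' @return a [LocalTree-class].
#' @export
localTreeFromPhylo <- function(phy, interval = c(0, 1)) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo object")
  if (!ape::is.binary(phy)) stop("tree must be binary")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  n <- length(phy$tip.label)
  m <- 2L * n - 1L
  depth <- ape::node.depth.edgelength(phy)   # distance from root
  times <- max(depth) - depth
  times[abs(times) < 1e-9 * max(depth)] <- 0 # snap float residue at the tips
  parent <- integer(m)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  localTree(parent, times, labels = phy$tip.label, interval = interval)
}

#' Convert a LocalTree to an ape phylo
#'
#' @param tree a [LocalTree-class].
#' @return an [ape::phylo] with branch lengths in generations.
#' @export
asPhylo <- function(tree) {
  n <- nLeaves(tree)
  m <- length(tree@parent)
  child <- which(tree@parent != 0L)
  # ape expects root = n + 1; renumber internal nodes by decreasing time
  internal <- (n + 1L):m
  ord <- internal[order(-tree@times[internal])]
  remap <- integer(m)
  remap[seq_len(n)] <- seq_len(n)
  remap[ord] <- (n + 1L):m
  edge <- cbind(remap[tree@parent[child]], remap[child])
  len <- tree@times[tree@parent[child]] - tree@times[child]
  phy <- list(edge = edge, edge.length = len, tip.label = tree@labels,
              Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}
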