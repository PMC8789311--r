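#' Read local genealogies from Newick plus an interval sidecar
#'
#' Reads one tree per genomic interval from a Newick file (branch lengths in
#' generations) and a BED-like sidecar (tab-separated columns: chrom, start,
#' end, tree index into the Newick file, 0-based half-open coordinates).
#' Intervals must tile the region: gaps and overlaps are rejected.
#'
#' @param newickPath path to a file of Newick trees, one per line.
#' @param intervalsPath path to the interval sidecar.
#' @param tolerance leaf-time tolerance: leaves further than this from time 0
#'   (as a fraction of tree height) trigger a validation error.
#' @return ordered list of [LocalTree-class].
#' @export
readLocalTrees <- function(newickPath, intervalsPath, tolerance = 1e-4) {
  phys <- ape::read.tree(newickPath)
  if (inherits(phys, "phylo")) phys <- list(phys)
  iv <- utils::read.table(intervalsPath, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "tree"))
  iv <- iv[order(iv$start), ]
  if (any(iv$start >= iv$end))
    stop("invalid interval (start >= end) in ", intervalsPath)
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
    stop("overlapping intervals in ", intervalsPath)
  if (nrow(iv) > 1 && any(iv$start[-1] > iv$end[-nrow(iv)]))
    stop("interval gap in ", intervalsPath)
  lapply(seq_len(nrow(iv)), function(i) {
    k <- iv$tree[i] + 1L                     # sidecar indexes trees 0-based
    if (k < 1L || k > length(phys))
      stop(sprintf("interval %d references missing tree %d", i, iv$tree[i]))
    tr <- localTreeFromPhylo(phys[[k]], interval = c(iv$start[i], iv$end[i]))
    bad <- abs(tr@times[seq_len(nLeaves(tr))]) >
      tolerance * max(tr@times)
    if (any(bad))
      stop(sprintf("tree for [%d, %d) is not ultrametric: %d leaf(s) off time 0",
                   iv$start[i], iv$end[i], sum(bad)))
    tr
  })
}

#' Write local genealogies as Newick plus an interval sidecar
#'
#' @param trees list of [LocalTree-class].
#' @param newickPath,intervalsPath output paths.
#' @param chrom chromosome/contig name for the sidecar.
#' @export
writeLocalTrees <- function(trees, newickPath, intervalsPath, chrom = "region") {
  phys <- lapply(trees, asPhylo)
  class(phys) <- "multiPhylo"
  ape::write.tree(phys, file = newickPath)
  iv <- data.frame(chrom = chrom,
                   start = vapply(trees, function(t) t@interval[1], numeric(1)),
                   end = vapply(trees, function(t) t@interval[2], numeric(1)),
                   tree = seq_along(trees) - 1L)
  utils::write.table(iv, intervalsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(newick = newickPath, intervals = intervalsPath))
}

#' Derived-allele carriers of a site from a phased VCF
#'
#' Looks up a biallelic SNP by its (1-based) VCF position, polarizes alleles
#' with the ancestral-allele INFO field (sites with a missing or invalid
#' field are rejected), and returns the haplotypes carrying the non-ancestral
#' allele. Haplotype numbering follows sample order, two haplotypes per
#' diploid sample; genotypes must be phased.
#'
#' @param vcfPath path to a VCF file.
#' @param position 1-based position of the site.
#' @param ancestralField INFO key holding the ancestral allele (default "AA").
#' @return a [SiteLabel-class]; its position is 0-based (internal convention).
#' @export
readCarriersVcf <- function(vcfPath, position, ancestralField = "AA") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readCarriersVcf requires the vcfR package")
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  pos <- as.integer(vcfR::getPOS(v))
  row <- which(pos == position)
  if (!length(row)) stop("no record at position ", position)
  if (length(row) > 1) stop("multiple records at position ", position)
  ref <- vcfR::getREF(v)[row]
  alt <- vcfR::getALT(v)[row]
  if (is.na(alt) || grepl(",", alt)) stop("site is not biallelic")
  info <- vcfR::extract.info(v, element = ancestralField)[row]
  if (is.na(info) || !nzchar(info))
    stop(sprintf("missing %s (ancestral allele) INFO field; site rejected",
                 ancestralField))
  aa <- toupper(sub("\\|.*", "", info))
  if (!aa %in% c(ref, alt))
    stop(sprintf("%s=%s matches neither REF (%s) nor ALT (%s); site rejected",
                 ancestralField, aa, ref, alt))
  gt <- vcfR::extract.gt(v, element = "GT")[row, ]
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype(s); phased haplotypes required")
  al <- unlist(strsplit(gt, "|", fixed = TRUE), use.names = FALSE)
  if (any(al == ".")) stop("missing allele call(s)")
  al <- as.integer(al)
  derivedCode <- if (aa == ref) 1L else 0L     # AA = ALT flips polarization
  carriers <- which(al == derivedCode)
  n <- length(al)
  if (!length(carriers) || length(carriers) == n)
    stop("site is monomorphic after polarization")
  siteLabel(position - 1L, carriers, n = n)
}

#' Write the hand-checkable fixture set
#'
#' Generates the small fixtures used in examples and tests: the 4-leaf toy
#' genealogy ((A,B):1,(C,D):2):3 as Newick with a 3-tree interval sidecar, an
#' 8-haplotype statistics block as CSV, a 20-region mini dataset container,
#' and a JSON table of expected statistic values computed from the package's
#' own functions (so regeneration can be checked for drift).
#'
#' @param outDir output directory (created).
#' @param seed RNG seed for the mini dataset.
#' @return invisibly, the list of written paths.
#' @export
makeFixtures <- function(outDir, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  toy <- toyTree()
  trees <- list(localTree(toy@parent, toy@times, toy@labels, c(0, 40)),
                localTree(toy@parent, toy@times * 1.5, toy@labels, c(40, 60)),
                localTree(toy@parent, toy@times * 2, toy@labels, c(60, 100)))
  writeLocalTrees(trees, file.path(outDir, "toy_trees.nwk"),
                  file.path(outDir, "toy_trees.intervals.tsv"), chrom = "toy")
  set.seed(seed)
  block <- matrix(rbinom(8 * 20, 1, 0.4), nrow = 8)
  utils::write.csv(block, file.path(outDir, "toy_block.csv"), row.names = FALSE)
  bs <- basicStats(block)
  gh <- garudH(block)
  expected <- list(basic = bs, garud = gh, zns = zns(block),
                   omegaMax = omegaMax(block))
  jsonlite::write_json(expected, file.path(outDir, "toy_block_expected.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ds <- makeDataset(nNeutral = 10, nSweep = 10, prior = priorSpec(),
                    demography = demographyConstant(2000), L = 2e4, n = 12L,
                    grid = buildTimeGrid(K = 32, tMax = 2e4), seed = seed)
  writeDataset(ds, file.path(outDir, "mini_dataset"))
  invisible(list.files(outDir, recursive = TRUE, full.names = TRUE))
}

#' The hand-checkable 4-leaf toy genealogy
#'
#' Leaves A..D at time 0; (A,B) join at generation 1, (C,D) at 2, root at 3.
#' Used throughout the documentation and tests because every lineage count
#' can be enumerated by hand.
#'
#' @param interval genomic interval to attach.
#' @return a [LocalTree-class].
#' @export
toyTree <- function(interval = c(0, 100)) {
  localTree(parent = c(5L, 5L, 6L, 6L, 7L, 7L, 0L),
            times = c(0, 0, 0, 0, 1, 2, 3),
            labels = c("A", "B", "C", "D"), interval = interval)
}
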