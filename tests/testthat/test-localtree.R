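# the toy genealogy: leaves A..D at 0, (A,B) join at 1, (C,D) at 2, root at 3

test_that("lineage counting follows the half-open convention with root clamp", {
  tr <- toyTree()
  expect_identical(countLineages(tr, 0), 4L)      # all leaf branches active
  expect_identical(countLineages(tr, 1.5), 3L)    # AB-ancestor, C, D
  expect_identical(countLineages(tr, 2.5), 2L)
  expect_identical(countLineages(tr, 1), 3L)      # at a node time: coalesced
  expect_identical(countLineages(tr, 3), 1L)      # root clamp
  expect_identical(countLineages(tr, 1e9), 1L)
})

test_that("mutation branch mapping finds the unique subtending branch", {
  tr <- toyTree()
  site <- siteLabel(10, c("A", "B"), labels = tr@labels)
  m <- mapMutationBranch(tr, site)
  expect_identical(sort(sweepnet:::.leafSet(tr, m)), c(1L, 2L))
  # single carrier maps to the leaf branch
  expect_identical(mapMutationBranch(tr, siteLabel(10, "C", labels = tr@labels)), 3L)
  # incompatible carrier set
  expect_error(mapMutationBranch(tr, siteLabel(10, c("A", "C"), labels = tr@labels)),
               "incompatible")
  # monomorphic carrier sets are contract violations
  expect_error(siteLabel(10, c("A", "B", "C", "D"), labels = tr@labels),
               "polymorphic")
  # best-match fallback picks the maximal-Jaccard branch instead of erroring
  bm <- mapMutationBranch(tr, siteLabel(10, c("A", "C"), labels = tr@labels),
                          bestMatch = TRUE)
  expect_true(bm %in% c(1L, 3L, 5L, 6L))
})

test_that("explicit branch maps take precedence over carrier matching", {
  tr <- toyTree()
  tr@branchMap <- list("10" = 6L)
  site <- siteLabel(10, c("A", "B"), labels = tr@labels)
  expect_identical(mapMutationBranch(tr, site), 6L)
})

test_that("ancestral/derived lineage classification matches hand enumeration", {
  tr <- toyTree()
  site <- siteLabel(10, c("A", "B"), labels = tr@labels)
  cl <- classifyLineages(tr, site, c(0, 1.5, 2.5, 3.5))
  expect_equal(unname(cl[, "anc"]), c(2, 2, 1, 1))
  expect_equal(unname(cl[, "der"]), c(2, 1, 1, 0))
  # anc + der conserves the total count everywhere
  expect_equal(rowSums(cl), as.numeric(countLineages(tr, c(0, 1.5, 2.5, 3.5))))
})

test_that("lineage counts agree with branch-interval enumeration on random trees", {
  set.seed(71)
  grid <- gridPoints(buildTimeGrid(K = 12, tMax = 4))
  for (rep in 1:60) {
    n <- sample(4:20, 1)
    tr <- randomCoalTree(n)
    car <- randomCladeCarriers(tr)
    site <- siteLabel(0.5, car, n = n)
    cl <- classifyLineages(tr, site, grid)
    for (j in seq_along(grid)) {
      expect_identical(countLineages(tr, grid[j]), oracleCountLineages(tr, grid[j]))
      oc <- oracleClassify(tr, car, grid[j])
      expect_identical(unname(cl[j, ]), unname(oc))
    }
  }
})

test_that("feature encoding is invariant to leaf relabeling", {
  set.seed(72)
  grid <- buildTimeGrid(K = 16, tMax = 3)
  tr <- randomCoalTree(8)
  car <- randomCladeCarriers(tr)
  fv1 <- extractFeatures(list(tr), 1, siteLabel(0.5, car, n = 8), grid)
  # permute leaf ids consistently (relabel leaves and carriers)
  perm <- sample(8)
  par2 <- tr@parent
  t2 <- tr@times
  # build a tree whose leaf i is old leaf perm[i]
  inv <- order(perm)
  map <- c(inv, 9:15)
  par2 <- integer(15)
  for (v in 1:15) {
    pv <- tr@parent[v]
    par2[map[v]] <- if (pv == 0L) 0L else map[pv]
  }
  t2 <- numeric(15); t2[map] <- tr@times
  tr2 <- localTree(par2, t2, labels = tr@labels[perm], interval = tr@interval)
  fv2 <- extractFeatures(list(tr2), 1, siteLabel(0.5, sort(inv[car]), n = 8), grid)
  expect_identical(featureValues(fv1), featureValues(fv2))
})

test_that("phylo round trip preserves topology and node times", {
  set.seed(73)
  tr <- randomCoalTree(10, interval = c(0, 50))
  phy <- asPhylo(tr)
  tr2 <- localTreeFromPhylo(phy, interval = c(0, 50))
  grid <- seq(0, treeTMRCA(tr) * 1.1, length.out = 25)
  expect_equal(countLineages(tr2, grid), countLineages(tr, grid))
  expect_equal(treeTMRCA(tr2), treeTMRCA(tr), tolerance = 1e-10)
})

test_that("LocalTree validity catches malformed trees", {
  expect_error(localTree(c(3L, 3L, 0L), c(0, 0, -1)), "older")
  expect_error(localTree(c(3L, 3L, 3L, 0L), c(0, 0, 0, 1)), "2n - 1|children")
  expect_error(localTree(c(5L, 5L, 6L, 6L, 7L, 7L, 0L),
                         c(0, 0, 0, 0, 1, 2, 3), interval = c(5, 5)), "interval")
})
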