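test_that("basic statistics match their closed-form toy values", {
  # two haplotypes differing at 3 of 5 sites
  m <- rbind(c(1, 0, 1, 0, 0), c(0, 0, 0, 1, 0))
  bs <- basicStats(m)
  expect_identical(bs$ss, 3L)
  expect_equal(bs$pi, 3)
  expect_equal(bs$thetaW, 3)           # a1 = 1 for n = 2
  expect_identical(bs$nHaplotypes, 2L)
  # monomorphic block
  m0 <- matrix(0L, 4, 6)
  bs0 <- basicStats(m0)
  expect_identical(bs0$ss, 0L)
  expect_equal(bs0$pi, 0)
  expect_true(is.na(bs0$tajimasD))
  expect_identical(bs0$nHaplotypes, 1L)
})

test_that("Garud H statistics match hand computations", {
  # two haplotype classes at 50/50
  m <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  gh <- garudH(m)
  expect_equal(gh$H1, 0.5)
  expect_equal(gh$H12, 1.0)
  # single class
  g1 <- garudH(matrix(1L, 5, 3))
  expect_equal(g1$H1, 1); expect_equal(g1$H12, 1); expect_equal(g1$H2H1, 0)
  # frequencies (0.6, 0.3, 0.1)
  m3 <- rbind(matrix(rep(c(0, 0), 6), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 1), 1), ncol = 2, byrow = TRUE))
  g3 <- garudH(m3)
  expect_equal(g3$H1, 0.46)
  expect_equal(g3$H12, 0.82)
  expect_equal(g3$H2H1, (0.46 - 0.36) / 0.46)
})

test_that("ZnS handles perfect correlation, independence and edge cases", {
  perf <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(zns(perf), 1)
  # orthogonal balanced columns -> r^2 = 0
  orth <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(zns(orth), 0)
  expect_true(is.na(zns(matrix(c(1, 0, 1, 0), 4, 1))))
})

test_that("every statistic agrees with its brute-force oracle on random blocks", {
  set.seed(51)
  for (rep in 1:40) {
    m <- matrix(rbinom(8 * 20, 1, runif(1, 0.2, 0.6)), nrow = 8)
    bs <- basicStats(m)
    expect_equal(bs$pi, oraclePi(m))
    expect_equal(bs$thetaW, oracleThetaW(m))
    expect_equal(bs$thetaH, oracleThetaH(m))
    expect_equal(bs$tajimasD, oracleTajimaD(m))
    gh <- garudH(m); og <- oracleGarud(m)
    expect_equal(gh$H1, og$H1)
    expect_equal(gh$H12, og$H12)
    expect_equal(gh$H2H1, og$H2H1)
    expect_equal(zns(m), oracleZns(m))
    expect_equal(omegaMax(m), oracleOmegaMax(m))
  }
})

test_that("omega evaluates exactly S-1 candidate splits", {
  set.seed(52)
  # 3 segregating sites -> 2 splits; verify against explicit enumeration
  m <- matrix(rbinom(8 * 3, 1, 0.5), nrow = 8)
  while (any(colSums(m) %in% c(0, 8))) m <- matrix(rbinom(8 * 3, 1, 0.5), nrow = 8)
  expect_equal(omegaMax(m), oracleOmegaMax(m))
  # two internally perfect-LD blocks with no cross-block LD -> large omega
  blockA <- c(1, 1, 1, 1, 0, 0, 0, 0)
  blockB <- c(1, 0, 1, 0, 1, 0, 1, 0)
  m2 <- cbind(blockA, blockA, blockB, blockB)
  expect_gt(omegaMax(m2), 100)
  expect_equal(omegaMax(m2), oracleOmegaMax(m2))
})

test_that("iHS behaves under symmetry and matches the EHH-integral oracle", {
  # symmetric block: derived and ancestral EHH decay identically
  m <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 0, 0), c(0, 0, 1))
  pos <- c(0, 50, 100)
  expect_equal(ihsSite(m, pos, 2), 0)
  set.seed(53)
  for (rep in 1:20) {
    m <- matrix(rbinom(8 * 15, 1, 0.5), nrow = 8)
    pos <- sort(runif(15, 0, 1e4))
    core <- 8L
    expect_equal(ihsSite(m, pos, core), oracleIhsSite(m, pos, core))
  }
})

test_that("region iHS standardizes within frequency bins", {
  set.seed(54)
  m <- matrix(rbinom(16 * 60, 1, 0.5), nrow = 16)
  pos <- sort(runif(60, 0, 5e4))
  res <- ihsRegion(m, pos, mafMin = 0.05, nBins = 10)
  expect_true(is.finite(res$score))
  expect_gt(nrow(res$sites), 10)
  # standardized scores have roughly zero mean and unit variance pooled
  expect_lt(abs(mean(res$sites$std)), 0.5)
  expect_lt(abs(sd(res$sites$std) - 1), 0.5)
  # MAF filter: monomorphic-ish block yields NA
  expect_true(is.na(ihsRegion(matrix(0L, 8, 5), 1:5)$score))
})

test_that("window features normalize to unit row sums in five windows", {
  set.seed(55)
  m <- matrix(rbinom(12 * 200, 1, 0.3), nrow = 12)
  pos <- sort(runif(200, 0, 1e5))
  wf <- windowFeatures(m, pos, start = 0, end = 1e5)
  expect_identical(dim(wf$normalized), c(11L, 5L))
  for (r in rownames(wf$normalized)) {
    v <- wf$normalized[r, ]
    if (all(is.finite(v))) expect_equal(sum(v), 1)
  }
  # scale invariance: scaling a raw row leaves normalized values unchanged
  raw2 <- wf$raw["pi", ] * 7.3
  expect_equal(raw2 / sum(raw2), wf$normalized["pi", ])
  # a statistic constant across windows normalizes to 0.2 everywhere
  ones <- matrix(1, 1, 5)
  expect_equal(as.numeric(ones / sum(ones)), rep(0.2, 5))
  # diversity concentrated in window 1
  m3 <- cbind(matrix(rbinom(12 * 50, 1, 0.5), nrow = 12))
  pos3 <- sort(runif(50, 0, 2e4))
  wf3 <- windowFeatures(m3, pos3, start = 0, end = 1e5)
  expect_equal(unname(wf3$normalized["pi", ]), c(1, 0, 0, 0, 0))
})

test_that("haplotype sorting follows the Manhattan-distance procedure", {
  # rows {000, 011, 001}: totals (3, 3, 2) -> row 3 first, then stable by distance
  m <- rbind(c(0, 0, 0), c(0, 1, 1), c(0, 0, 1))
  hs <- haplotypeSort(m)
  expect_identical(hs$order, c(3L, 1L, 2L))
  expect_identical(hs$matrix[1, ], c(0, 0, 1))
  # identical rows preserve original order (stable ties)
  mi <- matrix(1L, 4, 3)
  expect_identical(haplotypeSort(mi)$order, 1:4)
  # output rows are a permutation of input rows
  set.seed(56)
  mr <- matrix(rbinom(10 * 8, 1, 0.5), nrow = 10)
  hr <- haplotypeSort(mr)
  expect_identical(mr[hr$order, ], hr$matrix)
  expect_setequal(hr$order, 1:10)
})

test_that("genotype images have fixed size, centering and zero padding", {
  set.seed(57)
  m <- matrix(rbinom(198 * 400, 1, 0.3), nrow = 198)
  pos <- sort(runif(400, 0, 1e5))
  gi <- genotypeImage(m, pos, focalIndex = 200L, halfWidth = 180L)
  expect_identical(dim(gi$image), c(198L, 360L))
  expect_identical(length(gi$positions), 360L)
  expect_equal(gi$positions[181], pos[200])       # focal at column halfWidth + 1
  # sparse block: real columns surrounded by zero padding
  m2 <- matrix(rbinom(6 * 10, 1, 0.5), nrow = 6)
  gi2 <- genotypeImage(m2, 1:10, focalIndex = 5L, halfWidth = 20L)
  expect_identical(dim(gi2$image), c(6L, 40L))
  expect_identical(sum(gi2$positions != 0), 10L)   # all 10 real variants kept
  expect_equal(gi2$positions[21], 5)
  expect_true(all(gi2$image[, gi2$positions == 0] == 0))
})
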