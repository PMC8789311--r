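test_that("prior draws respect their ranges and are seed-reproducible", {
  spec <- priorSpec()
  set.seed(31)
  draws <- replicate(200, samplePriors(spec), simplify = FALSE)
  s <- vapply(draws, function(p) p@s, numeric(1))
  f <- vapply(draws, function(p) p@f, numeric(1))
  mu <- vapply(draws, function(p) p@mu, numeric(1))
  expect_true(all(s >= 1e-4 & s <= 0.02))
  expect_true(all(f >= 0.01 & f <= 0.99))
  expect_true(all(mu >= 1.25e-8 & mu <= 2.5e-8))
  set.seed(99); a <- samplePriors(spec)
  set.seed(99); b <- samplePriors(spec)
  expect_identical(a@s, b@s)
  expect_identical(a@f, b@f)
  # capuchino-like configuration draws soft sweeps with standing variation
  set.seed(31)
  pc <- samplePriors(priorSpecCapuchino())
  expect_identical(pc@mode, "soft")
  expect_true(pc@s >= 0.001 && pc@s <= 0.02)
  expect_true(pc@fInit < pc@f && pc@fInit <= 0.05)
  expect_error(priorSpec(sRange = c(0.02, 0.01)), "range")
})

test_that("built-in demographies expose coherent piecewise size histories", {
  d <- demographyCEU()
  # recent growth phases connect continuously to the founding bottleneck
  expect_equal(populationSize(d, 920 - 1e-9), 1032, tolerance = 1e-3)
  expect_equal(populationSize(d, 204.6), 9279.2, tolerance = 1e-3)
  expect_gt(populationSize(d, 0), 4e5)
  expect_equal(populationSize(d, 3000), 14474)
  expect_equal(populationSize(d, 1e4), 7310)
  cap <- demographyCapuchino()
  expect_equal(populationSize(cap, c(0, 1e5, 2e6)),
               c(130000, 14380000, 1450000))
  expect_error(demographyModel(data.frame(start = c(5, 0), size = 1)),
               "start")
})

test_that("conditioned trajectories satisfy their boundary conditions", {
  set.seed(32)
  dem <- demographyConstant(5000)
  for (rep in 1:20) {
    p <- sweepParams("hard", s = runif(1, 0.001, 0.05), f = runif(1, 0.1, 0.9))
    tr <- simulateTrajectory(p, dem)
    fr <- trajectoryFreqs(tr)
    expect_identical(fr[1], p@f)                       # starts at f
    expect_true(all(fr >= 0 & fr <= 1))
    expect_lte(fr[length(fr)], 1 / (2 * 4999))          # single founding copy
    expect_equal(tr@originGeneration, length(fr) - 1)
  }
  # soft mode: selection latches off below fInit going backward
  ps <- sweepParams("soft", s = 0.01, f = 0.6, fInit = 0.05)
  tr <- simulateTrajectory(ps, dem)
  expect_identical(trajectoryFreqs(tr)[1], 0.6)
})

test_that("neutral trajectory increments form a martingale", {
  set.seed(33)
  dem <- demographyConstant(5000)
  p <- sweepParams("hard", s = 0, f = 0.4)
  incs <- unlist(lapply(1:30, function(i)
    diff(trajectoryFreqs(simulateTrajectory(p, dem)))))
  expect_gt(length(incs), 10000)
  se <- sd(incs) / sqrt(length(incs))
  expect_lt(abs(mean(incs)), 4 * se + 1e-4)
})

test_that("sweep sojourn time tracks the deterministic logistic duration", {
  set.seed(34)
  dem <- demographyConstant(10000)
  p <- sweepParams("hard", s = 0.05, f = 0.95)
  soj <- replicate(150, {
    fr <- trajectoryFreqs(simulateTrajectory(p, dem))
    which(fr < 0.05)[1] - which(fr < 0.95)[1]
  })
  det <- 2 * log(19) / log(1.05)       # per-generation logistic crossing time
  expect_lt(abs(mean(soj) - det), max(3 * sd(soj) / sqrt(length(soj)), 0.01 * det))
})

test_that("simulated regions satisfy the schema invariants", {
  set.seed(35)
  dem <- demographyConstant(5000)
  p <- sweepParams("hard", s = 0.02, f = 0.7, mu = 2e-8, rho = 2e-8)
  r <- simulateRegion(p, dem, L = 2e4, n = 24L)
  expect_true(validObject(r))
  iv <- t(vapply(regionTrees(r), treeInterval, numeric(2)))
  expect_equal(iv[1, 1], 0)
  expect_equal(iv[nrow(iv), 2], 2e4)
  if (nrow(iv) > 1) expect_equal(iv[-1, 1], iv[-nrow(iv), 2])  # no gaps
  expect_true(!is.unsorted(r@positions))
  expect_identical(nrow(regionHaplotypes(r)), 24L)
  # focal site sits at L/2 with the derived leaves as carriers
  expect_identical(r@focalSite@position, 1e4)
  j <- which(r@positions == 1e4)
  expect_identical(which(regionHaplotypes(r)[, j] == 1L), r@focalSite@carriers)
  # truth consistency: sample DAF within binomial noise of truth f
  expect_lt(abs(daf(r@focalSite) - 0.7), 4 * sqrt(0.7 * 0.3 / 24) + 1 / 24)
  # the derived carriers form a clade of the focal genealogy
  foc <- regionTrees(r)[[treeIndexAt(r, 1e4)]]
  expect_silent(mapMutationBranch(foc, r@focalSite))
})

test_that("neutral coalescent calibration: TMRCA and diversity", {
  set.seed(36)
  dem <- demographyConstant(5000)
  p <- sweepParams("neutral", mu = 2e-8, rho = 2e-8)
  reps <- 400
  tm <- pi <- numeric(reps)
  for (i in 1:reps) {
    r <- simulateRegion(p, dem, L = 5e3, n = 16L)
    tm[i] <- treeTMRCA(regionTrees(r)[[treeIndexAt(r, 2.5e3)]])
    pi[i] <- basicStats(regionHaplotypes(r))$pi / r@L
  }
  expTM <- 4 * 5000 * (1 - 1 / 16)
  expect_lt(abs(mean(tm) - expTM), 3.5 * sd(tm) / sqrt(reps))
  expect_lt(abs(mean(pi) - 4 * 5000 * 2e-8) / (4 * 5000 * 2e-8), 0.05)
})

test_that("neutral site frequency spectrum is proportional to 1/i", {
  set.seed(5)
  dem <- demographyConstant(5000)
  p <- sweepParams("neutral", mu = 2e-8, rho = 2e-8)
  n <- 16
  sfs <- numeric(n - 1)
  for (i in 1:2000) {
    r <- simulateRegion(p, dem, L = 5e3, n = n)
    cnt <- colSums(regionHaplotypes(r))
    cnt <- cnt[cnt > 0 & cnt < n]
    if (length(cnt)) sfs <- sfs + tabulate(cnt, n - 1)
  }
  expP <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  chi <- sum((sfs - sum(sfs) * expP)^2 / (sum(sfs) * expP))
  expect_gt(pchisq(chi, n - 2, lower.tail = FALSE), 0.01)
})

test_that("sweeps depress central Tajima's D relative to neutral regions", {
  set.seed(6)
  dem <- demographyConstant(10000)
  reps <- 80
  dS <- dN <- numeric(reps)
  for (i in 1:reps) {
    rs <- simulateRegion(sweepParams("hard", s = 0.01, f = 0.9,
                                     mu = 1.5e-8, rho = 1.5e-8),
                         dem, L = 1e5, n = 32L)
    mid <- rs@positions >= 4e4 & rs@positions < 6e4
    dS[i] <- basicStats(regionHaplotypes(rs)[, mid, drop = FALSE])$tajimasD
    rn <- simulateRegion(sweepParams("neutral", mu = 1.5e-8, rho = 1.5e-8),
                         dem, L = 1e5, n = 32L)
    midn <- rn@positions >= 4e4 & rn@positions < 6e4
    dN[i] <- basicStats(regionHaplotypes(rn)[, midn, drop = FALSE])$tajimasD
  }
  expect_lt(mean(dS, na.rm = TRUE), mean(dN, na.rm = TRUE))
  expect_lt(t.test(dS, dN)$p.value, 0.001)
  # sweep regions also show faster derived-carrier coalescence at the focal tree
  expect_lt(abs(mean(dN, na.rm = TRUE)), 0.3)
})

test_that("DAF-matched neutral focal sites are drawn uniformly", {
  set.seed(37)
  dem <- demographyConstant(5000)
  r <- simulateRegion(sweepParams("neutral", mu = 5e-8, rho = 2e-8),
                      dem, L = 2e4, n = 16L)
  dafs <- colSums(regionHaplotypes(r)) / 16
  target <- 0.25
  ok <- which(abs(dafs - target) <= 0.1 & dafs > 0 & dafs < 1)
  expect_gt(length(ok), 2)
  draws <- replicate(1000, pickNeutralFocalSite(r, target, tolerance = 0.1)@position)
  tab <- table(factor(draws, levels = r@positions[ok]))
  chi <- suppressWarnings(chisq.test(tab))
  expect_gt(chi$p.value, 0.001)
  # degenerate tolerance admits any segregating site
  expect_s4_class(pickNeutralFocalSite(r, 0.5, tolerance = 0.5), "SiteLabel")
  # 0.47 is not a multiple of 1/16, so no site can match this tightly
  expect_error(pickNeutralFocalSite(r, 0.47, tolerance = 1e-9), "no segregating site")
  expect_error(pickNeutralFocalSite(
    simulateRegion(sweepParams("hard", s = 0.01, f = 0.5), dem, L = 5e3, n = 8L),
    0.5), "neutral")
})

test_that("trajectory discretization follows nearest-generation lookup", {
  fr <- seq(0.8, 0, length.out = 41)           # linear decay over 40 generations
  traj <- new("Trajectory", freqs = fr, originGeneration = 40)
  grid <- buildTimeGrid(K = 4, tMax = 100, curvature = 1)
  lab <- discretizeTrajectory(traj, grid)
  pts <- round(gridPoints(grid))
  expect_identical(lab[1], 0.8)                 # present-day frequency
  expect_identical(lab[4], 0)                   # older than the origin
  inside <- pts <= 40
  expect_equal(lab[inside], fr[pts[inside] + 1])
})

test_that("makeDataset honours counts, priors and seed reproducibility", {
  dem <- demographyConstant(2000)
  grid <- buildTimeGrid(K = 16, tMax = 2e4)
  ds <- makeDataset(nNeutral = 5, nSweep = 5, prior = priorSpec(),
                    demography = dem, L = 1e4, n = 12L, grid = grid, seed = 41)
  expect_identical(dim(ds$features), c(10L, 16L, 6L))
  expect_identical(sum(ds$labels$class == 1L), 5L)
  sw <- ds$labels$s[ds$labels$class == 1L]
  expect_true(all(sw >= 1e-4 & sw <= 0.02))
  expect_true(all(is.finite(ds$features)))
  ds2 <- makeDataset(nNeutral = 5, nSweep = 5, prior = priorSpec(),
                     demography = dem, L = 1e4, n = 12L, grid = grid, seed = 41)
  expect_identical(ds$labels, ds2$labels)
  expect_identical(ds$features, ds2$features)
  expect_identical(ds$meta$childSeeds, ds2$meta$childSeeds)
})
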