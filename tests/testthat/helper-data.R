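# Shared scaled-down experiment: one simulation bank and the trained models,
# built on first use and reused across test files. Conditions: constant
# N = 10,000, n = 32 haplotypes, L = 50 kb regions, true genealogies,
# s ~ U(0, 0.02), f ~ U(0.01, 0.99), mu, rho ~ U(1.25e-8, 2.5e-8); neutral
# focal sites DAF-matched to the sweep f prior. Sizes are desk-scale:
# 3,000 training + 500 held-out sweeps, 1,600 + 500 neutral regions, and
# fixed-s test panels at f = 0.8 for the power-ordering check.

.bankEnv <- new.env(parent = emptyenv())

scaledBankGrid <- function() buildTimeGrid()     # default K = 100, tMax = 1e5

scaledBank <- function() {
  if (!is.null(.bankEnv$bank)) return(.bankEnv$bank)
  dem <- demographyConstant(10000)
  grid <- scaledBankGrid()
  prior <- priorSpec(sRange = c(0, 0.02), fRange = c(0.01, 0.99))
  main <- makeDataset(nNeutral = 2100, nSweep = 3500, prior = prior,
                      demography = dem, L = 5e4, n = 32L, grid = grid,
                      seed = 4242)
  fixed <- lapply(c(0.001, 0.005, 0.01), function(s)
    makeDataset(nNeutral = 0, nSweep = 200,
                prior = priorSpec(sRange = c(s, s), fRange = c(0.8, 0.8)),
                demography = dem, L = 5e4, n = 32L, grid = grid,
                seed = 1000 + round(s * 1e5)))
  neutral08 <- makeDataset(nNeutral = 200, nSweep = 0,
                           prior = priorSpec(fRange = c(0.8, 0.8)),
                           demography = dem, L = 5e4, n = 32L, grid = grid,
                           seed = 77)
  ne <- which(main$labels$class == 0L)
  sw <- which(main$labels$class == 1L)
  .bankEnv$bank <- list(
    main = main, grid = grid,
    sweepTrain = sw[1:3000], sweepTest = sw[3001:3500],
    neutralTrain = ne[1:1600], neutralTest = ne[1601:2100],
    fixedS = setNames(fixed, c("s0.001", "s0.005", "s0.01")),
    neutral08 = neutral08)
  .bankEnv$bank
}

scaledRegressModel <- function() {
  if (!is.null(.bankEnv$regress)) return(.bankEnv$regress)
  b <- scaledBank()
  cfg <- netConfig("regress_s", unitsPerStack = 32, maxEpochs = 30,
                   dropoutRate = 0.1, patience = 6, batchSize = 64, seed = 5)
  .bankEnv$regress <- trainModel(b$main$features[b$sweepTrain, , ],
                                 b$main$labels$s[b$sweepTrain], cfg)
  .bankEnv$regress
}

scaledClassifyModel <- function() {
  if (!is.null(.bankEnv$classify)) return(.bankEnv$classify)
  b <- scaledBank()
  idx <- c(b$sweepTrain, b$neutralTrain)
  cfg <- netConfig("classify", unitsPerStack = 24, maxEpochs = 12,
                   dropoutRate = 0.2, patience = 4, batchSize = 64, seed = 6)
  .bankEnv$classify <- trainModel(b$main$features[idx, , ],
                                  b$main$labels$class[idx], cfg)
  .bankEnv$classify
}

scaledTrajectoryModel <- function() {
  if (!is.null(.bankEnv$traj)) return(.bankEnv$traj)
  b <- scaledBank()
  cfg <- netConfig("trajectory", unitsPerStack = 24, maxEpochs = 8,
                   dropoutRate = 0.1, patience = 3, batchSize = 64, seed = 8)
  .bankEnv$traj <- trainModel(b$main$features[b$sweepTrain, , ],
                              b$main$trajectories[b$sweepTrain, ], cfg)
  .bankEnv$traj
}
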