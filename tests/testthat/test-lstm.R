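test_that("network configuration defaults match the published architecture", {
  cfg <- netConfig("classify")
  expect_identical(cfg$nStacks, 2L)
  expect_identical(cfg$unitsPerStack, 100L)
  expect_equal(cfg$learningRate, 1e-3)
  expect_error(netConfig("classify", dropoutRate = 1), "dropoutRate")
  expect_error(netConfig("classify", nStacks = 0), "nStacks")
  w <- sweepnet:::.initWeights(6, c(100, 100), 2)
  expect_length(w$layers, 2)
  expect_identical(dim(w$layers[[1]]$Wx), c(6L, 400L))
  expect_identical(dim(w$layers[[2]]$Wx), c(100L, 400L))
})

test_that("shaped inputs reshape as K x C and round-trip", {
  v <- seq_len(600)
  m <- shapeInput(v, K = 100)
  expect_identical(dim(m), c(100L, 6L))
  expect_identical(as.numeric(m), as.numeric(v))
  expect_identical(dim(shapeInput(seq_len(200), K = 100)), c(100L, 2L))
})

test_that("analytic gradients match finite differences for every head", {
  set.seed(61)
  x <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  cube <- sweepnet:::.toCube(x, 1:4)
  for (task in c("regress", "trajectory", "classify")) {
    head <- if (task == "classify") 2L else 1L
    w <- sweepnet:::.initWeights(3, c(5, 5), head)
    y <- switch(task,
                regress = matrix(rnorm(4), 4, 1),
                trajectory = matrix(rnorm(24), 4, 6),
                classify = matrix(c(0, 1, 1, 0), 4, 1))
    g <- sweepnet:::lstm_grad_cpp(w, cube, y, task, 0)
    f <- function(wts) sweepnet:::lstm_grad_cpp(wts, cube, y, task, 0)$loss
    eps <- 1e-6
    w2 <- w; w2$layers[[1]]$Wx[2, 7] <- w2$layers[[1]]$Wx[2, 7] + eps
    expect_equal((f(w2) - f(w)) / eps, g$layers[[1]]$Wx[2, 7], tolerance = 1e-3)
    w2 <- w; w2$layers[[2]]$Wh[3, 11] <- w2$layers[[2]]$Wh[3, 11] + eps
    expect_equal((f(w2) - f(w)) / eps, g$layers[[2]]$Wh[3, 11], tolerance = 1e-3)
    w2 <- w; w2$Wo[4, head] <- w2$Wo[4, head] + eps
    expect_equal((f(w2) - f(w)) / eps, g$Wo[4, head], tolerance = 1e-3)
  }
})

test_that("classification separates a constructed two-class fixture", {
  set.seed(62)
  N <- 400; K <- 30; C <- 4
  x <- array(runif(N * K * C), c(N, K, C))
  cls <- rep(0:1, each = N / 2)
  x[cls == 1, , 2] <- x[cls == 1, , 2] + 0.5      # disjoint count signature
  idx <- sample(N)
  tr <- idx[1:320]; te <- idx[321:400]
  m <- trainModel(x[tr, , ], cls[tr],
                  netConfig("classify", unitsPerStack = 12, maxEpochs = 10,
                            dropoutRate = 0.1, seed = 1))
  p <- predict(m, x[te, , ])
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(rocAuroc(p, cls[te])$auroc, 0.95)
})

test_that("regression recovers a planted linear function of a channel mean", {
  set.seed(63)
  N <- 700; K <- 25; C <- 4
  x <- array(runif(N * K * C), c(N, K, C))
  y <- 0.002 + 0.05 * apply(x[, , 2], 1, mean)
  m <- trainModel(x[1:600, , ], y[1:600],
                  netConfig("regress_s", unitsPerStack = 24, maxEpochs = 150,
                            dropoutRate = 0, patience = 25,
                            learningRate = 2e-3, batchSize = 32, seed = 5))
  rm <- regressionMetrics(y[601:700], predict(m, x[601:700, , ]))
  expect_gte(rm$r2, 0.99)
})

test_that("trajectory task emits one clipped output per timepoint", {
  set.seed(64)
  N <- 150; K <- 20; C <- 3
  x <- array(runif(N * K * C), c(N, K, C))
  ytraj <- t(vapply(seq_len(N), function(i)
    pmin(1, pmax(0, cumsum(rnorm(K, 0, 0.05)) + x[i, 1, 1])), numeric(K)))
  m <- trainModel(x[1:120, , ], ytraj[1:120, ],
                  netConfig("trajectory", unitsPerStack = 8, maxEpochs = 5, seed = 2))
  p <- predict(m, x[121:150, , ])
  expect_identical(dim(p), c(30L, 20L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("point predictions are deterministic with dropout disabled", {
  set.seed(65)
  x <- array(runif(60 * 10 * 2), c(60, 10, 2))
  y <- runif(60, 0, 0.02)
  m <- trainModel(x, y, netConfig("regress_s", unitsPerStack = 6, maxEpochs = 2,
                                  dropoutRate = 0.3, seed = 3))
  p1 <- predict(m, x[1, , ])
  p2 <- predict(m, x[1, , ])
  expect_identical(p1, p2)
  expect_error(predict(m, x[1, 1:5, ]), "shape|match")
})

test_that("seeded training is reproducible", {
  set.seed(66)
  x <- array(runif(80 * 10 * 2), c(80, 10, 2))
  y <- runif(80, 0, 0.02)
  cfg <- netConfig("regress_s", unitsPerStack = 6, maxEpochs = 3, seed = 11)
  m1 <- trainModel(x, y, cfg)
  m2 <- trainModel(x, y, cfg)
  expect_identical(m1@log, m2@log)
  expect_identical(m1@weights$Wo, m2@weights$Wo)
})

test_that("Monte Carlo dropout contracts hold", {
  set.seed(67)
  x <- array(runif(80 * 10 * 2), c(80, 10, 2))
  y <- runif(80, 0, 0.02)
  # zero dropout: all samples identical, zero-width interval
  m0 <- trainModel(x, y, netConfig("regress_s", unitsPerStack = 6, maxEpochs = 2,
                                   dropoutRate = 0, seed = 4))
  pr0 <- predictWithDropout(m0, x[1, , ], nSamples = 20)
  expect_equal(diff(pr0@ci), 0)
  expect_equal(length(unique(pr0@samples)), 1L)
  # sample-count contract and interval ordering
  m <- trainModel(x, y, netConfig("regress_s", unitsPerStack = 6, maxEpochs = 2,
                                  dropoutRate = 0.3, seed = 4))
  pr <- predictWithDropout(m, x[1, , ], nSamples = 50, level = 0.9)
  expect_length(pr@samples, 50)
  expect_lte(pr@ci[1], pr@ci[2])
  expect_error(predictWithDropout(m, x[1, , ], nSamples = 1), "nSamples")
  # interval width non-decreasing in dropout rate on a fixed input
  width <- vapply(c(0.1, 0.3, 0.5), function(dr) {
    m@config$dropoutRate <- dr
    set.seed(100)
    mean(replicate(10, diff(predictWithDropout(m, x[1, , ], nSamples = 40)@ci)))
  }, numeric(1))
  expect_true(all(diff(width) >= -1e-9))
})

test_that("model checkpoints round-trip through save and load", {
  set.seed(68)
  x <- array(runif(40 * 8 * 2), c(40, 8, 2))
  y <- rep(0:1, 20)
  m <- trainModel(x, y, netConfig("classify", unitsPerStack = 5, maxEpochs = 2,
                                  seed = 9))
  dir <- file.path(tempdir(), "ckpt")
  saveModel(m, dir)
  m2 <- loadModel(dir)
  expect_identical(predict(m2, x), predict(m, x))
  expect_identical(m2@task, "classify")
  unlink(dir, recursive = TRUE)
})

test_that("label/task mismatches are rejected", {
  x <- array(runif(20 * 5 * 2), c(20, 5, 2))
  expect_error(trainModel(x, runif(20, 1, 2), netConfig("classify", seed = 1)),
               "0/1")
  expect_error(trainModel(x, runif(10), netConfig("regress_s", seed = 1)),
               "match")
})
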