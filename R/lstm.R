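#' Network configuration for the stacked-LSTM models
#'
#' Architecture and training hyperparameters. The defaults are a two-stacked
#' LSTM with 100 units per stack, hyperbolic-tangent activations, Adam with
#' its standard operating parameters, softmax head with cross-entropy loss
#' for classification and a linear head with mean-squared-error loss for the
#' regression and trajectory tasks. The trajectory task is many-to-many: the
#' model emits one output per time-grid point; all other tasks emit a single
#' output after the last timestep.
#'
#' @param task one of \code{"classify"}, \code{"regress_s"},
#'   \code{"regress_onset"}, \code{"trajectory"}.
#' @param nStacks number of LSTM stacks (default 2).
#' @param unitsPerStack LSTM units per stack (default 100).
#' @param dropoutRate inverted-dropout rate after each stack (default 0.2);
#'   also drives Monte Carlo dropout at inference.
#' @param batchSize minibatch size (default 64).
#' @param maxEpochs training epoch cap (default 40).
#' @param patience early-stopping patience on validation loss (default 5).
#' @param learningRate Adam step size (default 1e-3, the standard setting).
#' @param validationSplit held-out fraction when no explicit validation set is
#'   given (default 0.1).
#' @param seed RNG seed used for weight initialization, shuffling and dropout.
#' @return a list of class \code{"netConfig"}.
#' @export
netConfig <- function(task = c("classify", "regress_s", "regress_onset", "trajectory"),
                      nStacks = 2L, unitsPerStack = 100L, dropoutRate = 0.2,
                      batchSize = 64L, maxEpochs = 40L, patience = 5L,
                      learningRate = 1e-3, validationSplit = 0.1, seed = NULL) {
  task <- match.arg(task)
  stopifnot(nStacks >= 1L, unitsPerStack >= 1L,
            dropoutRate >= 0, dropoutRate < 1)
  structure(list(task = task, nStacks = as.integer(nStacks),
                 unitsPerStack = as.integer(unitsPerStack),
                 dropoutRate = dropoutRate, batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
                 learningRate = learningRate, validationSplit = validationSplit,
                 seed = seed),
            class = "netConfig")
}

# Glorot-uniform weights; LSTM forget-gate biases start at 1
.initWeights <- function(inputDim, units, headDim) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  layers <- list()
  cin <- inputDim
  for (u in units) {
    b <- numeric(4 * u)
    b[(u + 1):(2 * u)] <- 1
    layers[[length(layers) + 1L]] <-
      list(Wx = glorot(cin, 4 * u), Wh = glorot(u, 4 * u), b = matrix(b, 1))
    cin <- u
  }
  list(layers = layers, Wo = glorot(cin, headDim), bo = matrix(0, 1, headDim))
}

.flattenW <- function(w) {
  out <- list()
  for (l in seq_along(w$layers)) {
    out[[paste0("Wx", l)]] <- w$layers[[l]]$Wx
    out[[paste0("Wh", l)]] <- w$layers[[l]]$Wh
    out[[paste0("b", l)]]  <- w$layers[[l]]$b
  }
  out$Wo <- w$Wo; out$bo <- w$bo
  out
}

.unflattenW <- function(fl, nStacks) {
  layers <- lapply(seq_len(nStacks), function(l)
    list(Wx = fl[[paste0("Wx", l)]], Wh = fl[[paste0("Wh", l)]],
         b = fl[[paste0("b", l)]]))
  list(layers = layers, Wo = fl$Wo, bo = fl$bo)
}

.cppTask <- function(task) {
  switch(task, classify = "classify", trajectory = "trajectory", "regress")
}

# x: N x K x C array -> cube (B, C, K) for the C++ side
.toCube <- function(x, idx) {
  aperm(x[idx, , , drop = FALSE], c(1, 3, 2))
}

#' Train a stacked-LSTM selection-inference model
#'
#' Trains on lineage-count features with Adam and early stopping on a held-out
#' validation loss. Labels are taken from \code{y}: class labels in {0, 1}
#' for classification, selection coefficients or onset times (natural scale)
#' for regression, or an N x K matrix of grid-discretized allele frequencies
#' for the trajectory task. Regression targets are standardized internally
#' (the scaling is stored in the model and undone at prediction).
#'
#' @param x N x K x C feature array (e.g. \code{dataset$features}), or a
#'   \code{sweepDataset} (then \code{y} defaults to the task's truth label).
#' @param y labels; see Details.
#' @param config a [netConfig()].
#' @param xVal,yVal optional explicit validation data; otherwise
#'   \code{validationSplit} of the training data is held out.
#' @param verbose print per-epoch losses.
#' @return a [SweepModel-class].
#' @export
trainModel <- function(x, y = NULL, config = netConfig(), xVal = NULL,
                       yVal = NULL, verbose = FALSE) {
  meta <- list()
  if (inherits(x, "sweepDataset")) {
    ds <- x
    meta <- ds$meta
    x <- ds$features
    if (is.null(y))
      y <- switch(config$task,
                  classify = ds$labels$class,
                  regress_s = ds$labels$s,
                  regress_onset = ds$labels$onset,
                  trajectory = ds$trajectories)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  stopifnot(length(dim(x)) == 3L)
  N <- dim(x)[1]; K <- dim(x)[2]; C <- dim(x)[3]
  traj <- config$task == "trajectory"
  y <- if (traj) as.matrix(y) else matrix(as.numeric(y), ncol = 1)
  if (nrow(y) != N) stop("labels do not match the number of records")
  if (config$task == "classify" && !all(y %in% c(0, 1)))
    stop("classification labels must be 0/1")
  if (traj && ncol(y) != K) stop("trajectory labels must have one column per timepoint")

  center <- 0; scale <- 1
  if (config$task %in% c("regress_s", "regress_onset")) {
    center <- mean(y); scale <- stats::sd(y)
    if (!is.finite(scale) || scale == 0) scale <- 1
    y <- (y - center) / scale
  }

  if (is.null(xVal)) {
    nv <- max(1L, round(config$validationSplit * N))
    vi <- sample.int(N, nv)
    xVal <- x[vi, , , drop = FALSE]; yVal <- y[vi, , drop = FALSE]
    x <- x[-vi, , , drop = FALSE];   y <- y[-vi, , drop = FALSE]
    N <- dim(x)[1]
  } else {
    yVal <- if (traj) as.matrix(yVal) else matrix(as.numeric(yVal), ncol = 1)
    if (config$task %in% c("regress_s", "regress_onset"))
      yVal <- (yVal - center) / scale
  }

  headDim <- if (config$task == "classify") 2L else 1L
  w <- .initWeights(C, rep(config$unitsPerStack, config$nStacks), headDim)
  cppTask <- .cppTask(config$task)

  # Adam state over the flattened parameter list
  fl <- .flattenW(w)
  mAd <- lapply(fl, function(p) p * 0)
  vAd <- lapply(fl, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0

  valLoss <- function(wts) {
    cube <- .toCube(xVal, seq_len(dim(xVal)[1]))
    pred <- lstm_predict_cpp(wts, cube, cppTask, 0, FALSE)
    if (cppTask == "classify") {
      p <- pmax(pred[cbind(seq_len(nrow(pred)), yVal[, 1] + 1)], 1e-12)
      mean(-log(p))
    } else mean((pred - yVal)^2)
  }

  bestVal <- Inf; bestW <- w; bad <- 0
  log <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  nb <- ceiling(N / config$batchSize)
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample.int(N)
    tl <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * config$batchSize + 1):min(bi * config$batchSize, N)]
      g <- lstm_grad_cpp(w, .toCube(x, idx), y[idx, , drop = FALSE],
                         cppTask, config$dropoutRate)
      if (!is.finite(g$loss)) stop("training diverged: non-finite loss")
      tl <- tl + g$loss * length(idx)
      gf <- .flattenW(list(layers = g$layers, Wo = g$Wo, bo = g$bo))
      step <- step + 1
      lr <- config$learningRate * sqrt(1 - b2^step) / (1 - b1^step)
      flw <- .flattenW(w)
      for (nm in names(flw)) {
        mAd[[nm]] <- b1 * mAd[[nm]] + (1 - b1) * gf[[nm]]
        vAd[[nm]] <- b2 * vAd[[nm]] + (1 - b2) * gf[[nm]]^2
        flw[[nm]] <- flw[[nm]] - lr * mAd[[nm]] / (sqrt(vAd[[nm]]) + eps)
      }
      w <- .unflattenW(flw, config$nStacks)
    }
    vl <- valLoss(w)
    log <- rbind(log, data.frame(epoch = epoch, train = tl / N, val = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.6g  val %.6g", epoch, tl / N, vl))
    if (vl < bestVal - 1e-12) {
      bestVal <- vl; bestW <- w; bad <- 0
    } else {
      bad <- bad + 1
      if (bad >= config$patience) break
    }
  }

  new("SweepModel", weights = bestW, config = unclass(config),
      task = config$task, log = log,
      meta = c(meta[intersect(names(meta), c("grid", "channels", "normalized", "n"))],
               list(center = center, scale = scale, K = K, C = C)))
}

setMethod("show", "SweepModel", function(object) {
  cfg <- object@config
  cat(sprintf("SweepModel (%s): %d-stacked LSTM, %d units/stack, dropout %.2g\n",
              object@task, cfg$nStacks, cfg$unitsPerStack, cfg$dropoutRate))
  if (nrow(object@log))
    cat(sprintf("  trained %d epochs, best validation loss %.6g\n",
                nrow(object@log), min(object@log$val)))
})

.predictRaw <- function(model, x, dropout = 0, mc = FALSE) {
  if (is(x, "FeatureVector")) x <- array(featureValues(x), c(1, dim(featureValues(x))))
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  K <- model@meta$K; C <- model@meta$C
  if (dim(x)[2] != K || dim(x)[3] != C)
    stop(sprintf("feature shape %d x %d does not match the model's %d x %d",
                 dim(x)[2], dim(x)[3], K, C))
  cube <- .toCube(x, seq_len(dim(x)[1]))
  pred <- lstm_predict_cpp(model@weights, cube, .cppTask(model@task),
                           if (mc) model@config$dropoutRate else 0, mc)
  task <- model@task
  if (task == "classify") return(pred[, 2])                   # P(sweep)
  if (task == "trajectory") {                                 # B x K, clipped
    pred[pred < 0] <- 0
    pred[pred > 1] <- 1
    return(pred)
  }
  est <- pred[, 1] * model@meta$scale + model@meta$center
  if (task == "regress_s") est <- pmax(0, est)
  est
}

#' Predict from a trained model
#'
#' Deterministic point predictions (dropout disabled). Returns the sweep
#' probability (classify), the selection-coefficient or onset estimate
#' (regression; s clipped at 0), or a matrix of per-timepoint allele
#' frequencies clipped to [0, 1] (trajectory).
#'
#' @param object a [SweepModel-class].
#' @param x a [FeatureVector-class], a K x C matrix, or an N x K x C array.
#' @param ... unused.
#' @return numeric vector (or matrix for the trajectory task).
#' @export
setMethod("predict", "SweepModel", function(object, x, ...) {
  .predictRaw(object, x, mc = FALSE)
})

#' Monte Carlo dropout prediction with uncertainty interval
#'
#' Runs \code{nSamples} stochastic forward passes with dropout active
#' ("thinned" networks), and reports the empirical distribution of the
#' predictions together with a percentile confidence interval.
#'
#' @param model a [SweepModel-class] trained with a nonzero dropout rate (a
#'   zero rate yields identical samples and a zero-width interval).
#' @param x a single [FeatureVector-class] or K x C matrix.
#' @param nSamples number of dropout samples (default 100, >= 2).
#' @param level interval coverage (default 0.95).
#' @return a [Prediction-class].
#' @export
predictWithDropout <- function(model, x, nSamples = 100L, level = 0.95) {
  if (nSamples < 2L) stop("nSamples must be >= 2")
  point <- .predictRaw(model, x, mc = FALSE)
  if (model@task == "trajectory") {
    samples <- t(vapply(seq_len(nSamples),
                        function(i) .predictRaw(model, x, mc = TRUE)[1, ],
                        numeric(model@meta$K)))
    ci <- apply(samples, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    return(new("Prediction", task = model@task, point = as.numeric(point[1, ]),
               samples = samples, ci = ci, level = level))
  }
  samples <- vapply(seq_len(nSamples),
                    function(i) .predictRaw(model, x, mc = TRUE)[1],
                    numeric(1))
  ci <- stats::quantile(samples, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  new("Prediction", task = model@task, point = point[1],
      samples = samples, ci = ci, level = level)
}

setMethod("show", "Prediction", function(object) {
  if (object@task == "trajectory") {
    cat(sprintf("Prediction (trajectory): %d timepoints, present-day AF %.3f\n",
                length(object@point), object@point[1]))
  } else {
    cat(sprintf("Prediction (%s): %.6g", object@task, object@point))
    if (length(object@ci) == 2)
      cat(sprintf("  [%d%% CI %.6g, %.6g; %d dropout samples]",
                  round(object@level * 100), object@ci[1], object@ci[2],
                  length(object@samples)))
    cat("\n")
  }
})

#' Save / load a model checkpoint
#'
#' The checkpoint directory holds the weights (\code{weights.rds}) and a JSON
#' sidecar with the network configuration, time-grid parameters, channel
#' order and target scaling, so a checkpoint is self-describing.
#'
#' @param model a [SweepModel-class].
#' @param path checkpoint directory.
#' @export
saveModel <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model@weights, file.path(path, "weights.rds"))
  utils::write.csv(model@log, file.path(path, "training_log.csv"), row.names = FALSE)
  jsonlite::write_json(list(task = model@task, config = model@config,
                            meta = model@meta),
                       file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  side <- jsonlite::read_json(file.path(path, "config.json"), simplifyVector = TRUE)
  log <- utils::read.csv(file.path(path, "training_log.csv"))
  new("SweepModel", weights = readRDS(file.path(path, "weights.rds")),
      config = as.list(side$config), task = side$task, log = log,
      meta = as.list(side$meta))
}
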