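#' ROC curve and AUROC
#'
#' Sweeps the prediction threshold over every distinct score (tied scores
#' enter together), records the true- and false-positive rates, and computes
#' the area under the curve by the trapezoid rule.
#'
#' @param scores numeric prediction scores (higher = more sweep-like).
#' @param labels binary truth labels (1 = sweep).
#' @return list with \code{curve} (data.frame threshold, fpr, tpr) and
#'   \code{auroc}.
#' @export
rocAuroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("AUROC undefined: both classes must be present")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(th) + 1)
  for (i in seq_along(th)) {
    pos <- scores >= th[i]
    tpr[i + 1] <- sum(pos & labels == 1L) / P
    fpr[i + 1] <- sum(pos & labels == 0L) / N
  }
  auroc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(threshold = c(Inf, th), fpr = fpr, tpr = tpr),
       auroc = auroc)
}

#' Regression error metrics
#'
#' Mean absolute error, root mean square error, and the coefficient of
#' determination r2 = 1 - SS_res / SS_tot.
#'
#' @param yTrue,yPred numeric vectors of equal length (>= 2).
#' @return named list with mae, rmse, r2.
#' @export
regressionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2L) stop("need at least 2 observations")
  res <- yPred - yTrue
  sst <- sum((yTrue - mean(yTrue))^2)
  list(mae = mean(abs(res)), rmse = sqrt(mean(res^2)),
       r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_)
}

#' Stratified evaluation report
#'
#' Bins test items by true selection coefficient and derived allele
#' frequency (the 4 x 4 layout used for stratified sweep benchmarks by
#' default) and reports regression metrics, and AUROC where classification
#' scores are supplied (each sweep cell is contrasted against all neutral
#' items), per cell. Empty cells are flagged, not dropped.
#'
#' @param s,dafs truth selection coefficients and frequencies per test item.
#' @param yPred regression predictions (optional).
#' @param scores,labels classification scores and binary labels (optional).
#' @param sBins,dafBins bin edges.
#' @return data.frame with one row per (s bin x DAF bin) cell.
#' @export
stratifyMetrics <- function(s, dafs, yPred = NULL, scores = NULL, labels = NULL,
                            sBins = c(0, 0.0025, 0.005, 0.0075, 0.02),
                            dafBins = c(0, 0.25, 0.5, 0.75, 1)) {
  sb <- cut(s, sBins, include.lowest = TRUE)
  db <- cut(dafs, dafBins, include.lowest = TRUE)
  cells <- expand.grid(sBin = levels(sb), dafBin = levels(db),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    idx <- which(sb == cells$sBin[i] & db == cells$dafBin[i])
    row <- data.frame(sBin = cells$sBin[i], dafBin = cells$dafBin[i],
                      n = length(idx), empty = length(idx) == 0L,
                      mae = NA_real_, rmse = NA_real_, r2 = NA_real_,
                      auroc = NA_real_)
    if (length(idx) >= 2L && !is.null(yPred)) {
      m <- regressionMetrics(s[idx], yPred[idx])
      row$mae <- m$mae; row$rmse <- m$rmse; row$r2 <- m$r2
    }
    if (!is.null(scores) && !is.null(labels)) {
      neut <- which(labels == 0L)
      pos <- idx[labels[idx] == 1L]
      if (length(pos) && length(neut))
        row$auroc <- rocAuroc(c(scores[pos], scores[neut]),
                              c(rep(1L, length(pos)), rep(0L, length(neut))))$auroc
    }
    row
  }))
  out
}

#' Robustness to simulation-parameter mismatch
#'
#' Evaluates a trained model, without retraining, on test sets simulated
#' under deliberately mismatched configurations (mutation/recombination
#' rates outside the training range, alternative demographies or effective
#' population sizes). One report per mismatch specification, with the
#' configuration recorded as provenance.
#'
#' @param model a [SweepModel-class] (task \code{regress_s} or
#'   \code{classify}).
#' @param specs list of specs; each a list with elements \code{name},
#'   \code{prior} ([priorSpec()]), \code{demography}
#'   ([DemographyModel-class]), and optionally \code{L}, \code{n},
#'   \code{nNeutral}, \code{nSweep}.
#' @param grid the [TimeGrid-class] the model was trained with.
#' @param seed master seed for the mismatch test sets.
#' @return named list of reports, each with \code{metrics} and \code{spec}.
#' @export
robustnessGrid <- function(model, specs, grid = buildTimeGrid(), seed = 1L) {
  out <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    ds <- makeDataset(nNeutral = sp$nNeutral %||% 0L,
                      nSweep = sp$nSweep %||% 100L,
                      prior = sp$prior, demography = sp$demography,
                      L = sp$L %||% 1e5, n = sp$n %||% 32L,
                      grid = grid, seed = seed + i)
    metrics <- if (model@task == "classify") {
      p <- predict(model, ds$features)
      list(auroc = rocAuroc(p, ds$labels$class)$auroc)
    } else {
      est <- predict(model, ds$features)
      sweepIdx <- ds$labels$class == 1L
      c(regressionMetrics(ds$labels$s[sweepIdx], est[sweepIdx]),
        list(biasMedian = stats::median(est[sweepIdx] - ds$labels$s[sweepIdx])))
    }
    list(name = sp$name %||% paste0("spec", i), metrics = metrics,
         spec = list(L = sp$L %||% 1e5, n = sp$n %||% 32L,
                     demography = sp$demography@name,
                     prior = unclass(sp$prior), seed = seed + i))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
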