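#' Construct a demographic model
#'
#' A piecewise population-size history. Epoch i spans
#' \code{[start[i], start[i+1])} generations before present with diploid size
#' \code{size[i]} at its recent edge and forward-time exponential growth rate
#' \code{growth[i]}, so the size at time t within the epoch is
#' \code{size[i] * exp(-growth[i] * (t - start[i]))}.
#'
#' @param epochs data.frame with columns \code{start} (generations before
#'   present, first row 0), \code{size} (diploid Ne), and optionally
#'   \code{growth} (per-generation rate, default 0).
#' @param name model identifier.
#' @return a [DemographyModel-class].
#' @export
demographyModel <- function(epochs, name = "custom") {
  epochs <- as.data.frame(epochs)
  if (is.null(epochs$growth)) epochs$growth <- 0
  epochs <- epochs[, c("start", "size", "growth")]
  new("DemographyModel", epochs = epochs, name = name)
}

#' Built-in demographic models
#'
#' \code{demographyConstant} is a single constant-size population.
#' \code{demographyCEU} is the standard three-epoch-plus-two-growth-phase
#' European (CEU-like) history of Tennessen et al. (2012), converted to
#' generations with a 25-year generation time: ancestral Ne 7,310; African
#' expansion to 14,474 at 5,920 generations; out-of-Africa bottleneck to
#' 1,861 at 2,040; European founding size 1,032 at 920 growing at 0.307% per
#' generation, accelerating to 1.95% per generation over the last ~205
#' generations (present-day Ne around 5e5). \code{demographyCapuchino} is a
#' capuchino-seedeater-like piecewise history: derived Ne 130,000 to 44,000
#' generations ago, ancestral Ne 14,380,000 back to the 1,850,000-generation
#' root, and root Ne 1,450,000 beyond.
#'
#' @param N diploid population size for the constant model.
#' @return a [DemographyModel-class].
#' @export
demographyConstant <- function(N = 10000) {
  demographyModel(data.frame(start = 0, size = N, growth = 0),
                  name = sprintf("constant-N%g", N))
}

#' @rdname demographyConstant
#' @export
demographyCEU <- function() {
  tEG  <- 5115 / 25      # 204.6 generations: accelerated growth phase
  tEU0 <- 920            # European founding
  tB   <- 2040           # out-of-Africa bottleneck
  tAF  <- 5920           # African expansion
  nEU1 <- 1032 * exp(0.00307 * (tEU0 - tEG))   # size when growth accelerates
  nNow <- nEU1 * exp(0.0195 * tEG)
  demographyModel(data.frame(
    start  = c(0,      tEG,     tEU0, tB,    tAF),
    size   = c(nNow,   nEU1,    1861, 14474, 7310),
    growth = c(0.0195, 0.00307, 0,    0,     0)), name = "CEU-like")
}

#' @rdname demographyConstant
#' @export
demographyCapuchino <- function() {
  demographyModel(data.frame(
    start  = c(0, 44000, 1850000),
    size   = c(130000, 14380000, 1450000),
    growth = c(0, 0, 0)), name = "capuchino-like")
}

#' @describeIn demographyModel diploid population size at time t (generations
#'   before present); vectorized over t.
#' @param model a [DemographyModel-class].
#' @param t time(s) in generations.
#' @export
populationSize <- function(model, t) {
  e <- model@epochs
  i <- findInterval(t, e$start)
  pmax(2, e$size[i] * exp(-e$growth[i] * (t - e$start[i])))
}

setMethod("show", "DemographyModel", function(object) {
  cat(sprintf("DemographyModel '%s': %d epoch(s)\n", object@name, nrow(object@epochs)))
  print(object@epochs, row.names = FALSE)
})
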