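#' Build a discretized time grid
#'
#' Constructs the grid of K time points (generations before present) on which
#' genealogies are encoded. Points follow a log1p-uniform rule,
#' \deqn{t_j = \frac{\exp\{(j/(K-1)) \log(1 + c\, t_{max})\} - 1}{c}, \quad j = 0, \dots, K-1,}
#' which places \code{points[1] = 0}, \code{points[K] = tMax}, and makes the
#' spacing non-decreasing with j, i.e. recent times are discretized most
#' finely. The curvature c controls how strongly points concentrate near the
#' present.
#'
#' @param K number of grid points (>= 2); default 100.
#' @param tMax oldest grid time in generations; default 1e5.
#' @param curvature positive density parameter; default 1.
#' @return a [TimeGrid-class].
#' @examples
#' g <- buildTimeGrid()
#' length(gridPoints(g))  # 100
#' @export
buildTimeGrid <- function(K = 100L, tMax = 1e5, curvature = 1.0) {
  if (!is.finite(K) || K < 2) stop("K must be a finite integer >= 2")
  if (!is.finite(tMax) || tMax <= 0) stop("tMax must be finite and > 0")
  if (!is.finite(curvature) || curvature <= 0) stop("curvature must be finite and > 0")
  K <- as.integer(K)
  j <- seq(0, 1, length.out = K)
  pts <- expm1(j * log1p(curvature * tMax)) / curvature
  pts[1] <- 0
  pts[K] <- tMax
  new("TimeGrid", points = pts, tMax = tMax, curvature = curvature)
}

#' Grid accessors
#'
#' @param grid a [TimeGrid-class].
#' @return \code{gridPoints} the vector of times; \code{gridSize} the number of
#'   points K.
#' @export
gridPoints <- function(grid) grid@points

#' @rdname gridPoints
#' @export
gridSize <- function(grid) length(grid@points)

setMethod("show", "TimeGrid", function(object) {
  cat(sprintf("TimeGrid: %d points, 0 .. %.6g generations (curvature %.3g)\n",
              length(object@points), object@tMax, object@curvature))
})
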