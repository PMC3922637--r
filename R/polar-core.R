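#' Construct a polar sampling grid
#'
#' Builds the bullseye sampling geometry: \code{nTheta} equal angular bins and
#' \code{nRadial} equal-width radial bins over the unit disc.  Per-cell area
#' weights follow the polar Jacobian, \eqn{w_{ij} = (r_j^2 - r_{j-1}^2) /
#' n_\theta} with \eqn{r_j = j / n_r}, and sum to 1 over the disc.  Area
#' weighting matters because defect extent is reported as percent of the left
#' ventricle and equal per-cell counting would over-represent the apex.
#'
#' @param nTheta integer >= 4, number of angular bins.
#' @param nRadial integer >= 2, number of radial bins.
#' @return A \linkS4class{PolarGrid}.
#' @examples
#' g <- makePolarGrid(64, 32)
#' sum(areaWeights(g))  # 1
#' @export
makePolarGrid <- function(nTheta = 64L, nRadial = 32L) {
  nTheta <- as.integer(nTheta)
  nRadial <- as.integer(nRadial)
  if (length(nTheta) != 1L || is.na(nTheta) || nTheta < 4L)
    stop("nTheta must be a single integer >= 4")
  if (length(nRadial) != 1L || is.na(nRadial) || nRadial < 2L)
    stop("nRadial must be a single integer >= 2")
  r <- (0:nRadial) / nRadial
  ring <- diff(r^2)                       # annulus areas, sum = 1
  w <- matrix(rep(ring / nTheta, nTheta), nrow = nRadial, ncol = nTheta)
  w <- w / sum(w)
  new("PolarGrid", nTheta = nTheta, nRadial = nRadial, areaWeight = w)
}

#' Construct a polar map
#'
#' @param values numeric matrix, rows = radial bins (apex first), columns =
#'   angular bins.
#' @param grid a \linkS4class{PolarGrid}; defaults to one matching
#'   \code{dim(values)}.
#' @param phase \code{"stress"}, \code{"rest"} or \code{"difference"}.
#' @param normalized logical, whether values are already percent of maximum.
#' @return A \linkS4class{PolarMap}.
#' @export
polarMap <- function(values, grid = NULL, phase = "stress",
                     normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(grid)) grid <- makePolarGrid(ncol(values), nrow(values))
  new("PolarMap", grid = grid, values = values, phase = phase,
      normalized = normalized)
}

#' @rdname normalizeUptake
#' @export
setMethod("normalizeUptake", "PolarMap", function(x) {
  m <- max(x@values)
  if (m <= 0)
    stop("degenerate input: map has no positive uptake to normalize against")
  if (x@normalized) return(x)
  new("PolarMap", grid = x@grid, values = 100 * x@values / m,
      phase = x@phase, normalized = TRUE)
})

#' Rest minus stress difference map
#'
#' Computes the per-cell difference rest - stress between two normalized maps
#' on the same grid.  Positive values mark cells whose perfusion recovers at
#' rest, i.e. reversible (ischemic) territory; the stage-2 delineation
#' thresholds this image.
#'
#' @param stress,rest normalized \linkS4class{PolarMap}s on the same grid.
#' @return A \linkS4class{PolarMap} with \code{phase = "difference"}.
#' @export
differenceMap <- function(stress, rest) {
  stopifnot(is(stress, "PolarMap"), is(rest, "PolarMap"))
  if (nTheta(stress) != nTheta(rest) || nRadial(stress) != nRadial(rest))
    stop("grid mismatch: stress is ", nRadial(stress), "x", nTheta(stress),
         ", rest is ", nRadial(rest), "x", nTheta(rest))
  if (!stress@normalized || !rest@normalized)
    stop("both maps must be normalized (percent of maximum) first")
  new("PolarMap", grid = stress@grid, values = rest@values - stress@values,
      phase = "difference", normalized = FALSE)
}

## Cell-centre coordinates on the grid: theta in degrees, r as fraction of
## the outer radius.  Column i spans [(i-1), i) * 360/nTheta; row j spans
## [(j-1), j) / nRadial.
cellCenters <- function(grid) {
  th <- (seq_len(grid@nTheta) - 0.5) * 360 / grid@nTheta
  r <- (seq_len(grid@nRadial) - 0.5) / grid@nRadial
  list(theta = th, r = r)
}
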