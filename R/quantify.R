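#' Defect extent as percent of the left ventricle
#'
#' Area-weighted percent of the disc covered by the union of the region
#' masks.  The union prevents double counting of overlapping regions; an
#' empty region list has extent 0.
#'
#' @param regions list of \linkS4class{DefectRegion} (or logical mask
#'   matrices).
#' @param grid the \linkS4class{PolarGrid} the masks live on.
#' @return Extent in percent, in \[0, 100\].
#' @export
extentPercent <- function(regions, grid) {
  if (is(regions, "DefectRegion")) regions <- list(regions)
  if (!length(regions)) return(0)
  masks <- lapply(regions, function(r) {
    m <- if (is(r, "DefectRegion")) r@mask else r
    if (!is.logical(m)) m <- m != 0
    m
  })
  for (m in masks)
    if (!identical(dim(m), dim(grid@areaWeight)))
      stop("mask dimensions do not match the grid")
  u <- Reduce(`|`, masks)
  100 * sum(grid@areaWeight[u])
}

#' Default uptake-to-score bins
#'
#' Lower uptake bounds (percent of maximum) for scores 4, 3, 2, 1: mean
#' segment uptake >= 70 scores 0, 55-69 scores 1, 40-54 scores 2, 25-39
#' scores 3, below 25 scores 4.  These bins are the package's documented
#' stand-in for the normal-database scoring of commercial tools; they are
#' configurable and carry no published provenance.
#'
#' @return Numeric(4) of increasing bin edges \code{c(25, 40, 55, 70)}.
#' @export
defaultScoreBins <- function() c(25, 40, 55, 70)

#' Score a normalized map over the 17 segments
#'
#' Computes the area-weighted mean uptake per segment and bins it into a
#' 0 (normal) to 4 (absent uptake) score using \code{bins}.
#'
#' @param map a normalized \linkS4class{PolarMap}.
#' @param model a \linkS4class{SegmentModel17}.
#' @param bins increasing numeric(4) of bin edges (see
#'   [defaultScoreBins()]).
#' @return Integer(17) of segment scores.
#' @export
segmentScores <- function(map, model = segmentModel17(),
                          bins = defaultScoreBins()) {
  stopifnot(is(map, "PolarMap"), length(bins) == 4L, all(diff(bins) > 0))
  if (!map@normalized) map <- normalizeUptake(map)
  seg <- segmentMap(map@grid, model)
  w <- map@grid@areaWeight
  v <- map@values
  means <- vapply(1:17, function(s) {
    sel <- seg == s
    sum(v[sel] * w[sel]) / sum(w[sel])
  }, numeric(1))
  as.integer(4L - findInterval(means, bins))
}

#' Combine stress and rest segment scores
#'
#' Builds a \linkS4class{SegmentScores} object with the summed stress score
#' (SSS), summed rest score (SRS) and summed difference score (SDS).  SDS
#' sums the per-segment positive part \eqn{\max(stress_i - rest_i, 0)}, so
#' segments scored worse at rest never reduce it.
#'
#' @param stressScores,restScores integer(17) each, values in 0..4.
#' @return A \linkS4class{SegmentScores}.
#' @export
summedScores <- function(stressScores, restScores) {
  stressScores <- as.integer(stressScores)
  restScores <- as.integer(restScores)
  ok <- function(s) length(s) == 17L && !anyNA(s) && all(s >= 0L & s <= 4L)
  if (!ok(stressScores) || !ok(restScores))
    stop("scores must be 17 integers in 0..4")
  new("SegmentScores", stressScores = stressScores, restScores = restScores,
      sss = sum(stressScores), srs = sum(restScores),
      sds = sum(pmax(stressScores - restScores, 0L)))
}

#' Summed difference score as percent of maximum
#'
#' SD% = 100 x SDS / 68, the summed difference score relative to the total
#' possible score from 17 segments (4 x 17 = 68), read as percent ischemic
#' myocardium.
#'
#' @param scores a \linkS4class{SegmentScores}, or a bare SDS integer.
#' @return Percent in \[0, 100\], unrounded.
#' @export
sdPercent <- function(scores) {
  sds <- if (is(scores, "SegmentScores")) scores@sds else scores
  stopifnot(sds >= 0, sds <= 68)
  100 * sds / 68
}

#' Quantify one study end to end
#'
#' Convenience wrapper: runs the two-stage delineation, then derives extent
#' (percent of LV from the difference defects) and the 17-segment scores
#' (SSS/SRS/SDS and SD%).  Extent and SD% are computed by independent
#' routes - the first from delineated areas, the second from binned segment
#' means - so a study can show a nonzero SD% with zero extent.
#'
#' @param stress,rest \linkS4class{PolarMap}s on the same grid.
#' @param params a [delineationParams()] list.
#' @param model a \linkS4class{SegmentModel17}.
#' @param bins score bins, see [defaultScoreBins()].
#' @return List with \code{extentPercent}, \code{sdPercent}, \code{scores}
#'   (a \linkS4class{SegmentScores}) and \code{delineation} (the
#'   [delineate()] result).
#' @export
quantifyStudy <- function(stress, rest, params = delineationParams(),
                          model = segmentModel17(),
                          bins = defaultScoreBins()) {
  del <- delineate(stress, rest, params)
  sc <- summedScores(segmentScores(normalizeUptake(stress), model, bins),
                     segmentScores(normalizeUptake(rest), model, bins))
  list(extentPercent = del$extentPercent, sdPercent = sdPercent(sc),
       scores = sc, delineation = del)
}
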