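## Anchor table for the default 17-segment layout.  Angles in degrees,
## 0 at 3 o'clock, counterclockwise; intervals are half-open [lo, hi).
## Bands: 1 = apex (r in [0, 0.25)), 2 = apical, 3 = mid, 4 = basal.
.aha17Table <- function() {
  data.frame(
    segment = 1:17,
    label = c("basal anterior", "basal anteroseptal", "basal inferoseptal",
              "basal inferior", "basal inferolateral", "basal anterolateral",
              "mid anterior", "mid anteroseptal", "mid inferoseptal",
              "mid inferior", "mid inferolateral", "mid anterolateral",
              "apical anterior", "apical septal", "apical inferior",
              "apical lateral", "apex"),
    band = c(rep(4L, 6), rep(3L, 6), rep(2L, 4), 1L),
    thetaLo = c(60, 120, 180, 240, 300, 0,
                60, 120, 180, 240, 300, 0,
                45, 135, 225, 315, 0),
    thetaHi = c(120, 180, 240, 300, 360, 60,
                120, 180, 240, 300, 360, 60,
                135, 225, 315, 405, 360),
    stringsAsFactors = FALSE
  )
}

#' The default 17-segment model
#'
#' AHA-style layout: four radial bands at radius fractions 0 / 0.25 / 0.5 /
#' 0.75 / 1 (apex, apical, mid, basal) with a 1 / 4 / 6 / 6 angular split.
#' Basal and mid rings hold six 60-degree segments anchored so that the
#' anterior segment spans 60-120 degrees (0 degrees at 3 o'clock,
#' counterclockwise); the apical ring holds four 90-degree segments anchored
#' at 45 degrees; segment 17 (apex) is the innermost band, full circle.
#' Any fixed documented layout supports the summed-score arithmetic; this one
#' is the package's published convention.
#'
#' @return A \linkS4class{SegmentModel17}.
#' @examples
#' m <- segmentModel17()
#' m@boundaries[17, ]
#' @export
segmentModel17 <- function() {
  new("SegmentModel17", boundaries = .aha17Table(),
      radialBreaks = c(0, 0.25, 0.5, 0.75, 1))
}

#' Segment membership of a grid cell
#'
#' Maps one cell (by its centre) to its AHA segment id.  The 17 segments
#' partition the disc, so every in-range cell maps to exactly one segment.
#'
#' @param grid a \linkS4class{PolarGrid}.
#' @param cell integer(2): (angular index, radial index), 1-based.
#' @param model a \linkS4class{SegmentModel17}.
#' @return Integer segment id in 1..17.
#' @export
segmentOf <- function(grid, cell, model = segmentModel17()) {
  i <- as.integer(cell[1]); j <- as.integer(cell[2])
  if (i < 1L || i > grid@nTheta || j < 1L || j > grid@nRadial)
    stop("cell (", i, ", ", j, ") out of range for ",
         grid@nTheta, " x ", grid@nRadial, " grid")
  segmentMap(grid, model)[j, i]
}

#' Full segment-assignment matrix for a grid
#'
#' @param grid a \linkS4class{PolarGrid}.
#' @param model a \linkS4class{SegmentModel17}.
#' @return Integer matrix (nRadial x nTheta) of segment ids 1..17.
#' @export
segmentMap <- function(grid, model = segmentModel17()) {
  cc <- cellCenters(grid)
  bnd <- model@boundaries
  breaks <- model@radialBreaks
  band <- findInterval(cc$r, breaks, rightmost.closed = TRUE)
  out <- matrix(NA_integer_, grid@nRadial, grid@nTheta)
  for (j in seq_len(grid@nRadial)) {
    rows <- bnd[bnd$band == band[j], , drop = FALSE]
    for (i in seq_len(grid@nTheta)) {
      th <- cc$theta[i]
      hit <- which((th >= rows$thetaLo & th < rows$thetaHi) |
                   (th + 360 >= rows$thetaLo & th + 360 < rows$thetaHi))
      out[j, i] <- rows$segment[hit[1L]]
    }
  }
  out
}

#' Area weight of each segment
#'
#' @param grid a \linkS4class{PolarGrid}.
#' @param model a \linkS4class{SegmentModel17}.
#' @return Numeric(17), per-segment area fractions summing to 1.
#' @export
segmentAreaWeights <- function(grid, model = segmentModel17()) {
  seg <- segmentMap(grid, model)
  w <- grid@areaWeight
  vapply(1:17, function(s) sum(w[seg == s]), numeric(1))
}
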