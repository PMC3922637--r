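#' PolarGrid: sampling geometry of a bullseye polar map
#'
#' A polar (bullseye) sampling lattice for the left ventricle: \code{nTheta}
#' angular bins times \code{nRadial} radial bins, apex at the centre, base at
#' the rim.  Radial spacing is equal, so cell area weights follow the polar
#' Jacobian: the weight of a cell in radial ring \eqn{j} is proportional to
#' \eqn{(r_{j}^2 - r_{j-1}^2)/n_\theta} with \eqn{r_j = j/n_r}, normalised to
#' sum to one over the disc.  Matrices indexed on the grid are stored with
#' rows = radial bins (row 1 innermost, apex) and columns = angular bins.
#' Angular origin is the 3-o'clock position, counterclockwise.
#'
#' @slot nTheta integer, number of angular bins (>= 4).
#' @slot nRadial integer, number of radial bins (>= 2).
#' @slot areaWeight numeric matrix (nRadial x nTheta) of per-cell area
#'   fractions; nonnegative, sums to 1, nondecreasing in the radial index.
#'
#' @seealso [makePolarGrid()]
#' @export
setClass("PolarGrid", representation(
  nTheta = "integer",
  nRadial = "integer",
  areaWeight = "matrix"
))

setValidity("PolarGrid", function(object) {
  msg <- character()
  if (length(object@nTheta) != 1L || object@nTheta < 4L)
    msg <- c(msg, "nTheta must be a single integer >= 4")
  if (length(object@nRadial) != 1L || object@nRadial < 2L)
    msg <- c(msg, "nRadial must be a single integer >= 2")
  w <- object@areaWeight
  if (!is.numeric(w) || nrow(w) != object@nRadial || ncol(w) != object@nTheta)
    msg <- c(msg, "areaWeight must be a numeric nRadial x nTheta matrix")
  else {
    if (any(w < 0)) msg <- c(msg, "areaWeight must be nonnegative")
    if (abs(sum(w) - 1) > 1e-9) msg <- c(msg, "areaWeight must sum to 1")
    if (nrow(w) >= 2L && any(diff(w) < -1e-12))
      msg <- c(msg, "areaWeight must be nondecreasing in the radial index")
  }
  if (length(msg)) msg else TRUE
})

#' PolarMap: a scalar uptake field on a polar grid
#'
#' Perfusion uptake sampled on a \linkS4class{PolarGrid}.  \code{phase}
#' records whether the map is a stress acquisition, a rest acquisition, or a
#' rest-minus-stress difference image.  Stress/rest values are nonnegative
#' counts or percent; a normalized map has maximum value 100 (percent of
#' maximum uptake).  Difference maps may be negative.
#'
#' @slot grid a \linkS4class{PolarGrid}.
#' @slot values numeric matrix (nRadial x nTheta), finite.
#' @slot phase one of \code{"stress"}, \code{"rest"}, \code{"difference"}.
#' @slot normalized logical flag; TRUE once values are percent of maximum.
#'
#' @seealso [polarMap()], [normalizeUptake()], [differenceMap()]
#' @export
setClass("PolarMap", representation(
  grid = "PolarGrid",
  values = "matrix",
  phase = "character",
  normalized = "logical"
))

setValidity("PolarMap", function(object) {
  msg <- character()
  v <- object@values
  g <- object@grid
  if (nrow(v) != g@nRadial || ncol(v) != g@nTheta)
    msg <- c(msg, "values matrix does not match grid dimensions")
  if (!all(is.finite(v))) return(c(msg, "values must be finite"))
  if (!(object@phase %in% c("stress", "rest", "difference")))
    msg <- c(msg, "phase must be 'stress', 'rest' or 'difference'")
  if (object@phase != "difference" && any(v < 0))
    msg <- c(msg, "stress/rest values must be nonnegative")
  if (isTRUE(object@normalized) && object@phase != "difference" &&
      abs(max(v) - 100) > 1e-6)
    msg <- c(msg, "a normalized stress/rest map must have maximum 100")
  if (length(msg)) msg else TRUE
})

#' SegmentModel17: the 17-segment anatomical model
#'
#' An AHA-style 17-segment partition of the bullseye: four radial bands
#' (apex / apical / mid / basal at radius fractions 0-0.25-0.5-0.75-1) with
#' 1/4/6/6 angular divisions.  The boundary table gives, per segment, the
#' radial band and the angular interval in degrees (0 deg at 3 o'clock,
#' counterclockwise).  The model partitions the disc: every grid cell maps to
#' exactly one segment, and segment 17 (apex) is the innermost band, full
#' circle.
#'
#' @slot boundaries data.frame with columns \code{segment}, \code{label},
#'   \code{band} (1 = apex innermost .. 4 = basal), \code{thetaLo},
#'   \code{thetaHi} (degrees, half-open interval \[lo, hi) modulo 360).
#' @slot radialBreaks numeric(5), the band break radii as fractions of the
#'   outer radius.
#'
#' @seealso [segmentModel17()], [segmentOf()]
#' @export
setClass("SegmentModel17", representation(
  boundaries = "data.frame",
  radialBreaks = "numeric"
))

setValidity("SegmentModel17", function(object) {
  b <- object@boundaries
  msg <- character()
  if (nrow(b) != 17L) msg <- c(msg, "boundary table must have 17 rows")
  if (!all(c("segment", "label", "band", "thetaLo", "thetaHi") %in% names(b)))
    msg <- c(msg, "boundary table missing required columns")
  if (length(object@radialBreaks) != 5L ||
      any(diff(object@radialBreaks) <= 0))
    msg <- c(msg, "radialBreaks must be 5 increasing values")
  if (length(msg)) msg else TRUE
})

#' DefectSpec: a parametric perfusion defect for simulation
#'
#' Describes one synthetic defect as a separable angular x radial profile
#' with a raised-cosine edge.  The profile is 1 in the core, falls to 0.5
#' exactly at the half-widths, and reaches 0 at half-width + edge softness
#' (full-width-half-maximum convention: the ground-truth mask is the set of
#' cells where the profile exceeds 0.5).
#'
#' @slot centerTheta angular centre, degrees.
#' @slot centerR radial centre, fraction of outer radius in \[0, 1\].
#' @slot halfWidthTheta angular half width, degrees (> 0).
#' @slot halfWidthR radial half width, fraction of outer radius (> 0).
#' @slot severity fractional uptake reduction at the core, in \[0, 1\].
#' @slot reversibility fraction of the stress reduction recovered at rest,
#'   in \[0, 1\].
#' @slot edgeSoftness transition half-width (radius fractions / the same in
#'   degrees after scaling by 180); the profile ramps over
#'   \[halfWidth - softness, halfWidth + softness\].
#'
#' @seealso [defectSpec()], [simulateStudy()]
#' @export
setClass("DefectSpec", representation(
  centerTheta = "numeric",
  centerR = "numeric",
  halfWidthTheta = "numeric",
  halfWidthR = "numeric",
  severity = "numeric",
  reversibility = "numeric",
  edgeSoftness = "numeric"
))

setValidity("DefectSpec", function(object) {
  msg <- character()
  inunit <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!inunit(object@severity)) msg <- c(msg, "severity must be in [0,1]")
  if (!inunit(object@reversibility))
    msg <- c(msg, "reversibility must be in [0,1]")
  if (!inunit(object@centerR)) msg <- c(msg, "centerR must be in [0,1]")
  if (object@halfWidthTheta <= 0 || object@halfWidthR <= 0)
    msg <- c(msg, "half widths must be > 0")
  if (object@edgeSoftness < 0) msg <- c(msg, "edgeSoftness must be >= 0")
  if (object@centerR + object@halfWidthR > 1 + 1e-9)
    msg <- c(msg, "defect extends beyond the disc (centerR + halfWidthR > 1)")
  if (length(msg)) msg else TRUE
})

#' Contour: a closed active-contour polygon of circular topology
#'
#' Vertices are stored in grid-cell coordinates (theta index, radial index),
#' ordered counterclockwise around the originating seed, with the angular
#' coordinate unwrapped around the seed.  The fit is star-shaped about the
#' seed, so the polygon is closed, non-self-intersecting, and contains its
#' seed.
#'
#' @slot vertices numeric matrix (K x 2), columns \code{theta}, \code{r} in
#'   cell coordinates; K >= 8.
#' @slot seed numeric(2), the originating (theta, r) cell coordinates.
#' @slot energyTrace numeric, total energy per iteration (non-increasing).
#' @slot converged logical; FALSE when the iteration cap was reached before
#'   the energy tolerance.
#'
#' @seealso [fitActiveContour()]
#' @export
setClass("Contour", representation(
  vertices = "matrix",
  seed = "numeric",
  energyTrace = "numeric",
  converged = "logical"
))

setValidity("Contour", function(object) {
  msg <- character()
  if (nrow(object@vertices) < 8L) msg <- c(msg, "contour needs >= 8 vertices")
  if (ncol(object@vertices) != 2L) msg <- c(msg, "vertices must be K x 2")
  if (length(object@seed) != 2L) msg <- c(msg, "seed must be length 2")
  if (length(msg)) msg else TRUE
})

#' DefectRegion: a delineated defect region
#'
#' A boolean cell mask with provenance: stage-1 regions (\code{kind
#' "stress_defect"}) come from active contours fit to the stress map;
#' stage-2 regions (\code{kind "difference_defect"}) are strictly reversible
#' sub-regions obtained by smoothing and thresholding the rest-stress
#' difference inside stress defects, and are mask-only (their \code{contours}
#' list carries the parent contours, possibly empty).
#'
#' @slot mask logical matrix (nRadial x nTheta), at least one TRUE cell.
#' @slot contours list of \linkS4class{Contour} objects (provenance; may be
#'   empty for stage-2 regions).
#' @slot kind \code{"stress_defect"} or \code{"difference_defect"}.
#'
#' @seealso [delineate()], [extentPercent()]
#' @export
setClass("DefectRegion", representation(
  mask = "matrix",
  contours = "list",
  kind = "character"
))

setValidity("DefectRegion", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!any(object@mask)) msg <- c(msg, "mask must be nonempty")
  if (!(object@kind %in% c("stress_defect", "difference_defect")))
    msg <- c(msg, "kind must be 'stress_defect' or 'difference_defect'")
  if (length(msg)) msg else TRUE
})

#' SegmentScores: 17-segment perfusion scores and summed scores
#'
#' Integer scores 0 (normal) to 4 (absent uptake) per AHA segment for stress
#' and rest, with the derived summed stress score (SSS), summed rest score
#' (SRS) and summed difference score (SDS).  SDS sums the per-segment
#' positive part max(stress - rest, 0), so segments scored worse at rest do
#' not reduce it; 0 <= SDS <= 68 (= 4 x 17, the maximum possible score).
#'
#' @slot stressScores integer(17) in 0..4.
#' @slot restScores integer(17) in 0..4.
#' @slot sss integer, sum of stress scores.
#' @slot srs integer, sum of rest scores.
#' @slot sds integer, summed positive-part difference.
#'
#' @seealso [summedScores()], [sdPercent()]
#' @export
setClass("SegmentScores", representation(
  stressScores = "integer",
  restScores = "integer",
  sss = "integer",
  srs = "integer",
  sds = "integer"
))

setValidity("SegmentScores", function(object) {
  msg <- character()
  ok17 <- function(s) length(s) == 17L && all(s >= 0L & s <= 4L)
  if (!ok17(object@stressScores)) msg <- c(msg, "stressScores must be 17 values in 0..4")
  if (!ok17(object@restScores)) msg <- c(msg, "restScores must be 17 values in 0..4")
  if (length(msg)) return(msg)
  if (object@sss != sum(object@stressScores)) msg <- c(msg, "sss != sum(stressScores)")
  if (object@srs != sum(object@restScores)) msg <- c(msg, "srs != sum(restScores)")
  sds <- sum(pmax(object@stressScores - object@restScores, 0L))
  if (object@sds != sds) msg <- c(msg, "sds != sum(max(stress - rest, 0))")
  if (length(msg)) msg else TRUE
})

#' RaterPanel: a patients x observers matrix of extent values
#'
#' A complete two-way panel of defect-extent readings (percent of left
#' ventricle): one row per patient, one column per observer, no missing
#' cells.  Used by the agreement statistics (ICC, between-observer SD).
#'
#' @slot values numeric matrix, patients x observers, in percent.
#' @slot patientIds character, row labels.
#' @slot observerIds character, column labels.
#' @slot nClipped integer, number of cells clipped to \[0, 100\] during
#'   simulation (0 for observed data); clipping biases ICC, so it is
#'   reported rather than silent.
#'
#' @seealso [raterPanel()], [simulateRaterPanel()], [iccTwoWayRandom()]
#' @export
setClass("RaterPanel", representation(
  values = "matrix",
  patientIds = "character",
  observerIds = "character",
  nClipped = "integer"
))

setValidity("RaterPanel", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) < 2L || ncol(v) < 2L)
    msg <- c(msg, "panel needs >= 2 patients and >= 2 observers")
  if (any(!is.finite(v))) msg <- c(msg, "panel must be complete (no missing cells)")
  if (length(object@patientIds) != nrow(v)) msg <- c(msg, "patientIds length mismatch")
  if (length(object@observerIds) != ncol(v)) msg <- c(msg, "observerIds length mismatch")
  if (length(msg)) msg else TRUE
})

#' ICCResult: intraclass correlation from a two-way random-effects model
#'
#' Single-rater, absolute-agreement ICC from the two-way random-effects
#' decomposition (patients and observers random): \eqn{ICC = \sigma^2_p /
#' (\sigma^2_p + \sigma^2_o + \sigma^2_e)} with variance components from the
#' ANOVA mean squares (negative estimates truncated to zero) and a 95\%
#' F-based confidence interval.
#'
#' @slot icc numeric in \[0, 1\].
#' @slot ciLow,ciHigh numeric, 95 percent confidence bounds.
#' @slot varPatient,varObserver,varError numeric, variance components
#'   (percentage points squared), truncated at 0.
#' @slot degenerate logical; TRUE for a constant panel (icc defined as 1
#'   with CI \[1, 1\]).
#'
#' @seealso [iccTwoWayRandom()]
#' @export
setClass("ICCResult", representation(
  icc = "numeric",
  ciLow = "numeric",
  ciHigh = "numeric",
  varPatient = "numeric",
  varObserver = "numeric",
  varError = "numeric",
  degenerate = "logical"
))

setValidity("ICCResult", function(object) {
  msg <- character()
  if (object@ciLow > object@icc + 1e-12 || object@ciHigh < object@icc - 1e-12)
    msg <- c(msg, "CI must bracket the point estimate")
  if (min(object@varPatient, object@varObserver, object@varError) < 0)
    msg <- c(msg, "variance components must be >= 0 after truncation")
  if (length(msg)) msg else TRUE
})

#' BlandAltmanResult: agreement between two measurement methods
#'
#' Differences test - reference with mean bias and 1.96 SD limits of
#' agreement, plus the per-point boundary of the maximum possible difference
#' implied by extents lying in \[0, 100\]: for a reference value x, no
#' difference below -x (nor above 100 - x) is attainable, which appears as
#' the diagonal limit line in the plots.
#'
#' @slot bias numeric, mean difference (percentage points).
#' @slot loaLow,loaHigh numeric, bias -/+ 1.96 x sample SD of differences.
#' @slot differences numeric, per-point differences.
#' @slot means numeric, per-point (reference + test) / 2.
#' @slot maxDiffLower,maxDiffUpper numeric, per-point attainable difference
#'   bounds (-reference and 100 - reference).
#'
#' @seealso [blandAltman()]
#' @export
setClass("BlandAltmanResult", representation(
  bias = "numeric",
  loaLow = "numeric",
  loaHigh = "numeric",
  differences = "numeric",
  means = "numeric",
  maxDiffLower = "numeric",
  maxDiffUpper = "numeric"
))

setValidity("BlandAltmanResult", function(object) {
  if (object@loaLow > object@bias + 1e-12 || object@loaHigh < object@bias - 1e-12)
    "limits of agreement must bracket the bias" else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "PolarGrid", function(object) {
  cat("PolarGrid:", object@nTheta, "angular x", object@nRadial,
      "radial bins (apex at centre)\n")
})

setMethod("show", "PolarMap", function(object) {
  v <- object@values
  cat(sprintf("PolarMap [%s%s]: %d x %d cells, range [%.3g, %.3g]\n",
              object@phase, if (object@normalized) ", normalized" else "",
              object@grid@nRadial, object@grid@nTheta, min(v), max(v)))
})

setMethod("show", "DefectRegion", function(object) {
  cat(sprintf("DefectRegion [%s]: %d cells, %d contour(s)\n",
              object@kind, sum(object@mask), length(object@contours)))
})

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour: %d vertices, %d iterations, final energy %.4g%s\n",
              nrow(object@vertices), length(object@energyTrace),
              utils::tail(object@energyTrace, 1L),
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "SegmentScores", function(object) {
  cat(sprintf("SegmentScores: SSS %d, SRS %d, SDS %d (SD%% %.1f)\n",
              object@sss, object@srs, object@sds, 100 * object@sds / 68))
})

setMethod("show", "RaterPanel", function(object) {
  cat(sprintf("RaterPanel: %d patients x %d observers%s\n",
              nrow(object@values), ncol(object@values),
              if (object@nClipped > 0L)
                sprintf(" (%d values clipped to [0,100])", object@nClipped)
              else ""))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f-%.3f)%s\n",
              object@icc, object@ciLow, object@ciHigh,
              if (object@degenerate) " [degenerate panel]" else ""))
  cat(sprintf("  variance components: patient %.3f, observer %.3f, error %.3f\n",
              object@varPatient, object@varObserver, object@varError))
})

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf("Bland-Altman: bias %.3f, limits of agreement [%.3f, %.3f], n = %d\n",
              object@bias, object@loaLow, object@loaHigh,
              length(object@differences)))
})

## ---- accessors ----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("nTheta", "PolarGrid", function(x) x@nTheta)
#' @rdname accessors
#' @export
setMethod("nRadial", "PolarGrid", function(x) x@nRadial)
#' @rdname accessors
#' @export
setMethod("areaWeights", "PolarGrid", function(x) x@areaWeight)
#' @rdname accessors
#' @export
setMethod("nTheta", "PolarMap", function(x) x@grid@nTheta)
#' @rdname accessors
#' @export
setMethod("nRadial", "PolarMap", function(x) x@grid@nRadial)
#' @rdname accessors
#' @export
setMethod("areaWeights", "PolarMap", function(x) x@grid@areaWeight)
#' @rdname accessors
#' @export
setMethod("polarGrid", "PolarMap", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("mapValues", "PolarMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("mapPhase", "PolarMap", function(x) x@phase)
#' @rdname accessors
#' @export
setMethod("isNormalized", "PolarMap", function(x) x@normalized)
#' @rdname accessors
#' @export
setMethod("regionMask", "DefectRegion", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("regionKind", "DefectRegion", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("regionContours", "DefectRegion", function(x) x@contours)
#' @rdname accessors
#' @export
setMethod("contourVertices", "Contour", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("energyTrace", "Contour", function(x) x@energyTrace)
#' @rdname accessors
#' @export
setMethod("panelValues", "RaterPanel", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("patientIds", "RaterPanel", function(x) x@patientIds)
#' @rdname accessors
#' @export
setMethod("observerIds", "RaterPanel", function(x) x@observerIds)
#' @rdname accessors
#' @export
setMethod("nClipped", "RaterPanel", function(x) x@nClipped)
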