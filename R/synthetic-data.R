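#' Construct a parametric defect specification
#'
#' @param centerTheta angular centre in degrees (0 at 3 o'clock,
#'   counterclockwise).
#' @param centerR radial centre as fraction of outer radius, in \[0, 1\].
#' @param halfWidthTheta angular half width in degrees.
#' @param halfWidthR radial half width (radius fraction).
#' @param severity fractional uptake reduction at the core, \[0, 1\].
#' @param reversibility fraction of the stress reduction recovered at rest.
#' @param edgeSoftness raised-cosine transition half-width in radius
#'   fractions; the angular transition uses the same value scaled by 180
#'   degrees per unit radius, which is isotropic in cells on the default
#'   64 x 32 grid.
#' @return A \linkS4class{DefectSpec}.
#' @export
defectSpec <- function(centerTheta, centerR, halfWidthTheta, halfWidthR,
                       severity, reversibility, edgeSoftness = 0.05) {
  new("DefectSpec", centerTheta = as.numeric(centerTheta),
      centerR = as.numeric(centerR),
      halfWidthTheta = as.numeric(halfWidthTheta),
      halfWidthR = as.numeric(halfWidthR),
      severity = as.numeric(severity),
      reversibility = as.numeric(reversibility),
      edgeSoftness = as.numeric(edgeSoftness))
}

## Raised-cosine edge profile along one axis: 1 for d <= hw - soft, 0 for
## d >= hw + soft, cosine ramp between; exactly 0.5 at d = hw (FWHM edge).
.edgeProfile <- function(d, hw, soft) {
  if (soft <= 0) return(as.numeric(d < hw))
  u <- (d - (hw - soft)) / (2 * soft)
  p <- ifelse(u <= 0, 1, ifelse(u >= 1, 0, 0.5 * (1 + cos(pi * u))))
  p
}

## Separable defect profile over grid cell centres: min of the angular and
## radial edge profiles, so profile > 0.5 iff the cell centre lies strictly
## inside both half-widths.
.defectProfile <- function(grid, spec) {
  cc <- cellCenters(grid)
  dth <- abs((outer(rep(1, grid@nRadial), cc$theta) - spec@centerTheta + 180) %% 360 - 180)
  dr <- abs(outer(cc$r, rep(1, grid@nTheta)) - spec@centerR)
  softTheta <- spec@edgeSoftness * 180
  pt <- .edgeProfile(dth, spec@halfWidthTheta, softTheta)
  pr <- .edgeProfile(dr, spec@halfWidthR, spec@edgeSoftness)
  pmin(pt, pr)
}

#' Simulate a stress/rest polar-map study with known ground truth
#'
#' Builds a stress/rest pair over a uniform baseline of 100: inside each
#' defect the stress uptake is reduced by \code{severity x profile} and the
#' rest uptake by \code{severity x (1 - reversibility) x profile}, where the
#' profile has a raised-cosine edge (1 at the core, 0.5 at the half-widths).
#' Overlapping defects combine multiplicatively.  Multiplicative Gaussian
#' noise (SD = \code{noiseLevel} x signal) is then applied with the given
#' seed, standing in for Poisson count noise after reconstruction.
#'
#' Ground truth follows the full-width-half-maximum convention: the stress
#' defect mask holds the cells where any defect's noise-free profile exceeds
#' 0.5 (reduction above half the core severity); the reversible mask
#' restricts this to defects with \code{reversibility > 0}.  The true extent
#' is the area-weighted percent of the reversible mask.
#'
#' @param grid a \linkS4class{PolarGrid}.
#' @param defects list of \linkS4class{DefectSpec} (or a single spec).
#' @param noiseLevel nonnegative multiplicative noise SD (e.g. 0.05).
#' @param seed integer random seed; identical seeds give identical studies.
#' @return List with elements \code{stress}, \code{rest} (raw-count
#'   \linkS4class{PolarMap}s), and \code{truth}: a list with
#'   \code{stressDefectMask}, \code{reversibleMask} (logical matrices) and
#'   \code{trueExtentPercent}.
#' @examples
#' g <- makePolarGrid(64, 32)
#' d <- defectSpec(90, 0.75, 45, 0.25, severity = 0.6, reversibility = 1)
#' st <- simulateStudy(g, d, noiseLevel = 0, seed = 1)
#' st$truth$trueExtentPercent  # 18.75: quarter sector over r in [0.5, 1]
#' @export
simulateStudy <- function(grid, defects, noiseLevel = 0.05, seed = 1L) {
  if (is(defects, "DefectSpec")) defects <- list(defects)
  stopifnot(length(noiseLevel) == 1L, noiseLevel >= 0)
  for (d in defects) validObject(d)

  stress <- matrix(1, grid@nRadial, grid@nTheta)
  rest <- matrix(1, grid@nRadial, grid@nTheta)
  stressMask <- matrix(FALSE, grid@nRadial, grid@nTheta)
  revMask <- matrix(FALSE, grid@nRadial, grid@nTheta)
  for (d in defects) {
    p <- .defectProfile(grid, d)
    stress <- stress * (1 - d@severity * p)
    rest <- rest * (1 - d@severity * (1 - d@reversibility) * p)
    core <- p > 0.5 & d@severity > 0
    stressMask <- stressMask | core
    if (d@reversibility > 0) revMask <- revMask | core
  }
  stress <- 100 * stress
  rest <- 100 * rest

  if (noiseLevel > 0) {
    withr::with_seed(as.integer(seed), {
      nc <- grid@nRadial * grid@nTheta
      stress <- stress * (1 + noiseLevel * matrix(stats::rnorm(nc), grid@nRadial))
      rest <- rest * (1 + noiseLevel * matrix(stats::rnorm(nc), grid@nRadial))
    })
    stress <- pmax(stress, 0)
    rest <- pmax(rest, 0)
  }

  list(
    stress = polarMap(stress, grid, phase = "stress"),
    rest = polarMap(rest, grid, phase = "rest"),
    truth = list(
      stressDefectMask = stressMask,
      reversibleMask = revMask,
      trueExtentPercent = 100 * sum(grid@areaWeight[revMask])
    )
  )
}

#' Construct a rater panel from a values matrix
#'
#' @param values numeric patients x observers matrix (complete).
#' @param patientIds,observerIds optional labels.
#' @param nClipped integer, cells clipped during simulation (default 0).
#' @return A \linkS4class{RaterPanel}.
#' @export
raterPanel <- function(values, patientIds = NULL, observerIds = NULL,
                       nClipped = 0L) {
  values <- as.matrix(values)
  if (is.null(patientIds)) patientIds <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(observerIds)) observerIds <- sprintf("O%02d", seq_len(ncol(values)))
  new("RaterPanel", values = values, patientIds = patientIds,
      observerIds = observerIds, nClipped = as.integer(nClipped))
}

#' Simulate a patients x observers extent panel
#'
#' Draws a complete two-way panel from the additive random-effects model
#' \eqn{y_{ij} = \mu + p_i + o_j + e_{ij}} with independent zero-mean normal
#' patient, observer and residual effects of the stated SDs.  The implied
#' single-rater ICC is \eqn{\sigma_p^2 / (\sigma_p^2 + \sigma_o^2 +
#' \sigma_e^2)}.  Values are clipped to \[0, 100\] (extents are percentages);
#' the number of clipped cells is recorded on the panel because clipping
#' biases the ICC.
#'
#' @param nPatients,nRaters panel dimensions (>= 2 each).
#' @param patientSd,raterSd,errorSd component SDs in percentage points.
#' @param grandMean mean extent in percent.
#' @param seed integer random seed.
#' @return A \linkS4class{RaterPanel}.
#' @examples
#' p <- simulateRaterPanel(25, 11, patientSd = 15, raterSd = 5, errorSd = 5,
#'                         grandMean = 20, seed = 1)
#' iccTwoWayRandom(p)
#' @export
simulateRaterPanel <- function(nPatients, nRaters, patientSd, raterSd,
                               errorSd, grandMean = 20, seed = 1L) {
  stopifnot(nPatients >= 2L, nRaters >= 2L,
            patientSd >= 0, raterSd >= 0, errorSd >= 0)
  vals <- withr::with_seed(as.integer(seed), {
    p <- stats::rnorm(nPatients, 0, patientSd)
    o <- stats::rnorm(nRaters, 0, raterSd)
    e <- matrix(stats::rnorm(nPatients * nRaters, 0, errorSd),
                nPatients, nRaters)
    grandMean + outer(p, rep(1, nRaters)) + outer(rep(1, nPatients), o) + e
  })
  clipped <- sum(vals < 0 | vals > 100)
  vals <- pmin(pmax(vals, 0), 100)
  raterPanel(vals, nClipped = clipped)
}

#' Simulate a second read guided by a suggested delineation
#'
#' Models the effect of showing every observer a common computer-suggested
#' delineation: each reading is shrunk toward the per-patient reference value
#' with the given weight, \eqn{y'_{ij} = (1 - w) y_{ij} + w \, ref_i}.
#' Shrinkage toward a common reference removes observer-specific variance,
#' so the recovered ICC of the second read is expected to rise.
#'
#' @param panel a \linkS4class{RaterPanel} (the first read).
#' @param reference numeric vector of per-patient reference extents
#'   (recycled across observers).
#' @param weight shrinkage weight in \[0, 1\]; 0.5 by default.
#' @return A \linkS4class{RaterPanel}.
#' @export
simulateSecondRead <- function(panel, reference, weight = 0.5) {
  stopifnot(is(panel, "RaterPanel"), weight >= 0, weight <= 1)
  v <- panel@values
  if (length(reference) != nrow(v))
    stop("reference must have one value per patient")
  v2 <- (1 - weight) * v + weight * matrix(reference, nrow(v), ncol(v))
  raterPanel(v2, panel@patientIds, panel@observerIds, panel@nClipped)
}
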