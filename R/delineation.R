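#' Delineation parameters
#'
#' Tunable parameters of the two-stage delineation, with the package
#' defaults.  None of these constants come from a published source; they are
#' the package's documented configuration.
#'
#' @param depthThreshold percent of maximum uptake below which a local
#'   minimum qualifies as a seed (stage 1).
#' @param nVertices number of contour vertices (circular topology).
#' @param alpha membrane (first-difference) weight of the snake energy.
#' @param beta thin-plate (second-difference) weight.
#' @param gammaEdge weight of the gradient-magnitude edge attraction.
#' @param gammaIntensity weight of the region intensity term: the interior
#'   integral of (uptake - \code{intensityLevel}), so low uptake attracts
#'   the contour interior and uptake above the level repels it.
#' @param intensityLevel reference uptake (percent) for the region term;
#'   defaults to \code{depthThreshold}.
#' @param step vertex move length per greedy update, in cells.
#' @param maxIter iteration cap of the greedy descent.
#' @param tol energy-change tolerance for termination.
#' @param initRadius initial contour radius around the seed, in cells.
#' @param sigma Gaussian smoothing width (cells) for the stage-2 difference
#'   image; 0 disables smoothing.
#' @param revThreshold reversibility threshold (percentage points of
#'   smoothed rest - stress difference) for stage 2.
#' @param minAreaCells minimum region size in cells; smaller regions are
#'   discarded as noise.
#' @return A named list of parameters.
#' @export
delineationParams <- function(depthThreshold = 70, nVertices = 32,
                              alpha = 0.1, beta = 0.05, gammaEdge = 1.0,
                              gammaIntensity = 1.0,
                              intensityLevel = depthThreshold,
                              step = 1, maxIter = 500, tol = 1e-4,
                              initRadius = 1.5, sigma = 2,
                              revThreshold = 10, minAreaCells = 4) {
  list(depthThreshold = depthThreshold, nVertices = as.integer(nVertices),
       alpha = alpha, beta = beta, gammaEdge = gammaEdge,
       gammaIntensity = gammaIntensity, intensityLevel = intensityLevel,
       step = step, maxIter = as.integer(maxIter), tol = tol,
       initRadius = initRadius, sigma = sigma, revThreshold = revThreshold,
       minAreaCells = as.integer(minAreaCells))
}

## ---- lattice helpers ----------------------------------------------------
## The polar grid is treated as a Cartesian lattice, periodic in theta
## (columns) and bounded in r (rows).  Continuous coordinates are in cell
## units with cell centres at integers: (ti, rj) samples column ti, row rj.

.wrapCol <- function(i, nTheta) ((i - 1) %% nTheta) + 1

## Bilinear interpolation of matrix m at continuous (t, r); theta wraps,
## r clamps to [1, nRadial] (edge extension).
.sampleMap <- function(m, t, r) {
  nR <- nrow(m); nT <- ncol(m)
  r <- pmin(pmax(r, 1), nR)
  j0 <- pmin(floor(r), nR - 1L); fr <- r - j0
  i0 <- floor(t); ft <- t - i0
  c00 <- m[cbind(j0, .wrapCol(i0, nT))]
  c01 <- m[cbind(j0, .wrapCol(i0 + 1, nT))]
  c10 <- m[cbind(j0 + 1, .wrapCol(i0, nT))]
  c11 <- m[cbind(j0 + 1, .wrapCol(i0 + 1, nT))]
  (1 - fr) * ((1 - ft) * c00 + ft * c01) + fr * ((1 - ft) * c10 + ft * c11)
}

## Gradient magnitude by central differences; theta wraps, r one-sided at
## the apex and base rows.
.gradientMagnitude <- function(m) {
  nR <- nrow(m); nT <- ncol(m)
  gt <- (m[, .wrapCol(seq_len(nT) + 1, nT)] - m[, .wrapCol(seq_len(nT) - 1, nT)]) / 2
  gr <- m
  gr[2:(nR - 1), ] <- (m[3:nR, ] - m[1:(nR - 2), ]) / 2
  gr[1, ] <- m[2, ] - m[1, ]
  gr[nR, ] <- m[nR, ] - m[nR - 1, ]
  sqrt(gt^2 + gr^2)
}

#' Find seed points for stress-defect delineation
#'
#' Scans the normalized stress map for strict local minima in the
#' 8-neighbourhood (angular wrap-around respected, radial edges one-sided)
#' whose uptake lies below \code{depthThreshold}.  Equal-valued connected
#' plateau minima collapse to the plateau's centroid cell.
#'
#' @param map a normalized \linkS4class{PolarMap}.
#' @param depthThreshold seed depth criterion, percent of maximum.
#' @return Integer matrix with columns \code{theta}, \code{r} (one row per
#'   seed); zero rows when the map has no qualifying minima.
#' @export
findSeeds <- function(map, depthThreshold = 70) {
  stopifnot(is(map, "PolarMap"))
  if (!map@normalized) map <- normalizeUptake(map)
  v <- map@values
  nR <- nrow(v); nT <- ncol(v)

  ## neighbourhood min (excluding the centre): shift the matrix over the
  ## 8 offsets with theta wrap and r edge handling
  nbrMin <- matrix(Inf, nR, nT)
  nbrHasEqual <- matrix(FALSE, nR, nT)
  for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0) next
    cols <- .wrapCol(seq_len(nT) + di, nT)
    rows <- seq_len(nR) + dj
    keep <- rows >= 1 & rows <= nR
    sh <- matrix(Inf, nR, nT)
    sh[which(keep), ] <- v[rows[keep], cols]
    nbrMin <- pmin(nbrMin, sh)
    nbrHasEqual <- nbrHasEqual | (abs(sh - v) < 1e-12)
  }
  cand <- v <= nbrMin & v < depthThreshold
  if (!any(cand)) return(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("theta", "r"))))

  ## collapse plateau candidates: connected components of candidate cells
  ## with equal value -> centroid cell (circular mean over theta)
  lab <- .labelComponents(cand, byValue = v)
  seeds <- NULL
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)   # rows = (r, theta)
    ## plateau must be a strict minimum vs its surrounding ring
    val <- v[idx[1, 1], idx[1, 2]]
    border <- .componentBorderValues(v, lab == l)
    if (length(border) && min(border) <= val + 1e-12) next
    th <- .circularMeanIndex(idx[, 2], ncol(v))
    rr <- round(mean(idx[, 1]))
    seeds <- rbind(seeds, c(theta = as.integer(th), r = as.integer(rr)))
  }
  if (is.null(seeds)) seeds <- matrix(integer(0), 0, 2)
  colnames(seeds) <- c("theta", "r")
  seeds
}

## Connected components (8-connectivity, theta wrap) of a logical mask.
## When byValue is given, cells join a component only if their values are
## equal (plateau labelling).
.labelComponents <- function(mask, byValue = NULL) {
  nR <- nrow(mask); nT <- ncol(mask)
  lab <- matrix(0L, nR, nT)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      j <- (cell - 1L) %% nR + 1L
      i <- (cell - 1L) %/% nR + 1L
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        jj <- j + dj
        if (jj < 1 || jj > nR) next
        ii <- .wrapCol(i + di, nT)
        if (!mask[jj, ii] || lab[jj, ii] != 0L) next
        if (!is.null(byValue) &&
            abs(byValue[jj, ii] - byValue[j, i]) > 1e-12) next
        lab[jj, ii] <- cur
        queue <- c(queue, (ii - 1L) * nR + jj)
      }
    }
  }
  lab
}

## Values of cells bordering (8-neighbourhood, wrap) a component mask.
.componentBorderValues <- function(v, compMask) {
  nR <- nrow(v); nT <- ncol(v)
  border <- matrix(FALSE, nR, nT)
  idx <- which(compMask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    j <- idx[k, 1]; i <- idx[k, 2]
    for (dj in -1:1) for (di in -1:1) {
      jj <- j + dj
      if (jj < 1 || jj > nR) next
      ii <- .wrapCol(i + di, nT)
      if (!compMask[jj, ii]) border[jj, ii] <- TRUE
    }
  }
  v[border]
}

## Circular mean of angular indices (1-based), returned as nearest index.
.circularMeanIndex <- function(i, nT) {
  ang <- 2 * pi * (i - 1) / nT
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  (round(m / (2 * pi) * nT) %% nT) + 1
}

#' Fit an active contour of circular topology around a seed
#'
#' Initialises a small circle around the seed and greedily minimises
#' \deqn{E = \alpha \sum_k |v_{k+1} - v_k|^2 + \beta \sum_k |v_{k+1} - 2 v_k
#' + v_{k-1}|^2 - \gamma_{edge} \sum_k |\nabla I(v_k)| + \gamma_{int}
#' \int_{interior} (I - L) \, dA}
#' over the polar lattice treated as a theta-periodic Cartesian grid, where
#' \eqn{I} is the normalized uptake and \eqn{L} the reference level
#' (\code{intensityLevel}): the membrane and thin-plate terms keep the
#' polygon short and smooth, the edge term attracts vertices to high
#' gradient magnitude, and the region term makes low uptake attract the
#' contour interior while uptake above \eqn{L} repels it, so the contour
#' grows across flat defect cores and halts at the defect rim without an
#' ad-hoc balloon force.  The fit is star-shaped about the seed (each vertex
#' moves along a fixed ray), which guarantees a closed, non-self-intersecting
#' polygon containing its seed.  Greedy coordinate descent makes the energy
#' trace non-increasing; iteration stops when the energy change drops below
#' \code{tol} or at \code{maxIter} (then flagged unconverged).
#'
#' @param map a normalized stress \linkS4class{PolarMap}.
#' @param seed integer(2) or numeric(2): seed (theta, r) in cell indices,
#'   strictly inside the disc.
#' @param params a [delineationParams()] list.
#' @return A \linkS4class{Contour}.
#' @export
fitActiveContour <- function(map, seed, params = delineationParams()) {
  stopifnot(is(map, "PolarMap"))
  if (!map@normalized) map <- normalizeUptake(map)
  v <- map@values
  nR <- nrow(v); nT <- ncol(v)
  ts <- as.numeric(seed[1]); rs <- as.numeric(seed[2])
  if (rs <= 0.5 || rs >= nR + 0.5)
    stop("seed lies on or outside the disc boundary")
  G <- .gradientMagnitude(v)

  K <- params$nVertices
  phi <- 2 * pi * (seq_len(K) - 1) / K
  cphi <- cos(phi); sphi <- sin(phi)

  ## max radius per ray: keep r-coordinate in [0.6, nR + 0.4] and avoid
  ## wrapping past the far side of the theta axis
  rhoMax <- rep(nT / 2 - 1, K)
  up <- sphi > 1e-9; dn <- sphi < -1e-9
  rhoMax[up] <- pmin(rhoMax[up], (nR + 0.4 - rs) / sphi[up])
  rhoMax[dn] <- pmin(rhoMax[dn], (0.6 - rs) / sphi[dn])
  rhoMax <- pmax(rhoMax, 0.5)
  rho <- pmin(rep(params$initRadius, K), rhoMax)

  ## region term per ray: precompute cumulative integral
  ## Q_k(rho) = int_0^rho (I(seed + t dir_k) - L) * t * (2 pi / K) dt
  ## on a fine t lattice, so a vertex move changes only its own ray term.
  dt <- 0.25
  tGrid <- seq(dt / 2, max(rhoMax) + 1, by = dt)
  Qk <- matrix(0, length(tGrid) + 1L, K)
  for (k in seq_len(K)) {
    tt <- ts + tGrid * cphi[k]
    rr <- rs + tGrid * sphi[k]
    f <- (.sampleMap(v, tt, rr) - params$intensityLevel) * tGrid *
      (2 * pi / K) * dt
    Qk[, k] <- c(0, cumsum(f))
  }
  regionQ <- function(k, rhok) {
    ## linear interpolation of the cumulative integral at rho
    pos <- rhok / dt + 1
    i0 <- pmax(1L, pmin(floor(pos) + 1L, nrow(Qk) - 1L))
    fr <- pmin(pmax(pos + 1 - i0, 0), 1)
    Qk[i0, k] * (1 - fr) + Qk[i0 + 1L, k] * fr
  }

  xy <- function(rho) cbind(rho * cphi, rho * sphi)  # seed-local frame
  vertexImageE <- function(rho, k) {
    tt <- ts + rho * cphi[k]
    rr <- rs + rho * sphi[k]
    -params$gammaEdge * .sampleMap(G, tt, rr) +
      params$gammaIntensity * regionQ(k, rho)
  }
  totalEnergy <- function(rho) {
    p <- xy(rho)
    nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
    prv <- rbind(p[K, , drop = FALSE], p[-K, , drop = FALSE])
    memb <- sum((nxt - p)^2)
    bend <- sum((nxt - 2 * p + prv)^2)
    img <- sum(vapply(seq_len(K), function(k) vertexImageE(rho[k], k),
                      numeric(1)))
    params$alpha * memb + params$beta * bend + img
  }

  energy <- totalEnergy(rho)
  trace <- energy
  converged <- FALSE
  idxPrev <- function(k) if (k == 1L) K else k - 1L
  idxNext <- function(k) if (k == K) 1L else k + 1L

  ## greedy descent with step annealing: after converging at the nominal
  ## step the moves are halved twice, letting vertices settle on the
  ## gradient ridge to sub-cell precision
  stepSizes <- params$step * c(1, 0.5, 0.25)
  phase <- 1L
  for (iter in seq_len(params$maxIter)) {
    stp <- stepSizes[phase]
    for (k in seq_len(K)) {
      cands <- unique(pmin(pmax(rho[k] + c(-stp, 0, stp),
                                0.5), rhoMax[k]))
      if (length(cands) == 1L) next
      km1 <- idxPrev(k); kp1 <- idxNext(k)
      km2 <- idxPrev(km1); kp2 <- idxNext(kp1)
      pk <- function(kk, r = rho[kk]) c(r * cphi[kk], r * sphi[kk])
      localE <- function(rk) {
        p <- pk(k, rk)
        pm1 <- pk(km1); pp1 <- pk(kp1); pm2 <- pk(km2); pp2 <- pk(kp2)
        memb <- sum((p - pm1)^2) + sum((pp1 - p)^2)
        bend <- sum((p - 2 * pm1 + pm2)^2) + sum((pp1 - 2 * p + pm1)^2) +
          sum((pp2 - 2 * pp1 + p)^2)
        params$alpha * memb + params$beta * bend + vertexImageE(rk, k)
      }
      es <- vapply(cands, localE, numeric(1))
      best <- cands[which.min(es)]
      if (best != rho[k] && min(es) < localE(rho[k]) - 1e-12) rho[k] <- best
    }
    eNew <- totalEnergy(rho)
    trace <- c(trace, eNew)
    settled <- abs(energy - eNew) < params$tol
    energy <- eNew
    if (settled) {
      if (phase == length(stepSizes)) { converged <- TRUE; break }
      phase <- phase + 1L
    }
  }

  verts <- cbind(theta = ts + rho * cphi, r = rs + rho * sphi)
  new("Contour", vertices = verts, seed = c(ts, rs), energyTrace = trace,
      converged = converged)
}

#' Rasterize a contour to a cell mask
#'
#' A cell belongs to the mask when its centre lies inside the polygon
#' (even-odd rule).  The polygon's angular coordinate is unwrapped once
#' around its seed, and cell centres are mapped into the same window, so
#' contours crossing the 0/360-degree cut rasterize correctly.
#'
#' @param contour a \linkS4class{Contour}.
#' @param grid a \linkS4class{PolarGrid}.
#' @return Logical matrix (nRadial x nTheta).
#' @export
rasterizeContour <- function(contour, grid) {
  nR <- grid@nRadial; nT <- grid@nTheta
  ts <- contour@seed[1]
  px <- contour@vertices[, 1] - ts          # unwrapped about the seed
  py <- contour@vertices[, 2]
  mask <- matrix(FALSE, nR, nT)
  xs <- ((seq_len(nT) - ts + nT / 2) %% nT) - nT / 2   # offsets in (-nT/2, nT/2]
  for (i in seq_len(nT)) {
    if (abs(xs[i]) > max(abs(px)) + 1) next
    mask[, i] <- .pointInPolygon(xs[i], seq_len(nR), px, py)
  }
  mask
}

## Even-odd rule for a column of points (x fixed, vector of y).
.pointInPolygon <- function(x, ys, px, py) {
  K <- length(px)
  inside <- rep(FALSE, length(ys))
  jj <- K
  for (k in seq_len(K)) {
    x1 <- px[jj]; y1 <- py[jj]; x2 <- px[k]; y2 <- py[k]
    if ((x1 <= x) != (x2 <= x)) {
      yCross <- y1 + (x - x1) / (x2 - x1) * (y2 - y1)
      inside <- xor(inside, yCross > ys)
    }
    jj <- k
  }
  inside
}

#' Stage 1: delineate stress defects
#'
#' Runs [findSeeds()] on the normalized stress map and fits one active
#' contour per seed, deepest (lowest-uptake) seed first; a seed that falls
#' inside an already-delineated region is skipped, since its contour would
#' merge into that region anyway (noise creates clusters of local minima
#' inside one defect).  Each region mask is the rasterized contour united
#' with the seed's connected component of cells below
#' \code{depthThreshold}: a discrete polygon slightly undercuts the corners
#' of a plateau-shaped defect, and the sub-threshold component restores
#' that coverage while leaving smooth defects to the contour.  Regions
#' whose masks overlap by at least one cell are merged (union mask,
#' contours kept as provenance) and regions smaller than
#' \code{minAreaCells} are discarded.  Output masks are pairwise disjoint.
#'
#' @param map a stress \linkS4class{PolarMap} (normalized internally).
#' @param params a [delineationParams()] list.
#' @return List of \linkS4class{DefectRegion} of kind
#'   \code{"stress_defect"}; empty for a normal study.
#' @export
delineateStressDefects <- function(map, params = delineationParams()) {
  if (!map@normalized) map <- normalizeUptake(map)
  seeds <- findSeeds(map, params$depthThreshold)
  if (nrow(seeds) == 0L) return(list())
  deep <- .labelComponents(map@values < params$depthThreshold)
  seeds <- seeds[order(map@values[seeds[, c("r", "theta"), drop = FALSE]]), ,
                 drop = FALSE]
  covered <- matrix(FALSE, map@grid@nRadial, map@grid@nTheta)
  contours <- list()
  masks <- list()
  for (s in seq_len(nrow(seeds))) {
    if (covered[seeds[s, "r"], seeds[s, "theta"]]) next
    ct <- fitActiveContour(map, seeds[s, ], params)
    m <- rasterizeContour(ct, map@grid)
    seedLab <- deep[seeds[s, "r"], seeds[s, "theta"]]
    if (seedLab > 0L) m <- m | (deep == seedLab)
    if (!any(m)) next
    covered <- covered | m
    contours[[length(contours) + 1L]] <- ct
    masks[[length(masks) + 1L]] <- m
  }
  if (!length(masks)) return(list())

  ## merge overlapping masks (union-find)
  n <- length(masks)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (any(masks[[a]] & masks[[b]])) {
      ra <- findRoot(a); rb <- findRoot(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  regions <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    m <- Reduce(`|`, masks[members])
    if (sum(m) < params$minAreaCells) next
    regions[[length(regions) + 1L]] <-
      new("DefectRegion", mask = m, contours = contours[members],
          kind = "stress_defect")
  }
  regions
}

## Gaussian smoothing on the polar lattice: separable kernel, circular in
## theta, reflected at the radial edges.  sigma in cells; 0 = identity.
.gaussianSmoothPolar <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-rad:rad, sd = sigma)
  kern <- kern / sum(kern)
  nR <- nrow(m); nT <- ncol(m)
  ## theta (columns), circular
  out <- matrix(0, nR, nT)
  for (d in -rad:rad)
    out <- out + kern[d + rad + 1L] * m[, .wrapCol(seq_len(nT) + d, nT)]
  ## r (rows), reflected
  refl <- function(j) { j <- abs(j - 1) + 1; j <- ifelse(j > nR, 2 * nR - j + 1, j); j }
  out2 <- matrix(0, nR, nT)
  for (d in -rad:rad)
    out2 <- out2 + kern[d + rad + 1L] * out[refl(seq_len(nR) + d), ]
  out2
}

#' Stage 2: extract reversible difference defects
#'
#' Gaussian-smooths the rest - stress difference image (circular in theta),
#' then, within each stress-defect mask separately, selects cells whose
#' smoothed difference exceeds \code{revThreshold} and splits the selection
#' into connected components.  Cells outside all stress defects are never
#' selected, so every component is contained in its parent stress defect.
#' Components below \code{minAreaCells} are discarded.
#'
#' @param stressDefects list of stage-1 \linkS4class{DefectRegion}s.
#' @param diff the rest - stress difference \linkS4class{PolarMap}.
#' @param params a [delineationParams()] list (uses \code{sigma},
#'   \code{revThreshold}, \code{minAreaCells}).
#' @return List of \linkS4class{DefectRegion} of kind
#'   \code{"difference_defect"}.
#' @export
extractReversible <- function(stressDefects, diff,
                              params = delineationParams()) {
  stopifnot(is(diff, "PolarMap"))
  if (!length(stressDefects)) return(list())
  g <- diff@grid
  for (reg in stressDefects)
    if (!identical(dim(reg@mask), dim(diff@values)))
      stop("grid mismatch between stress defect masks and difference map")
  sm <- .gaussianSmoothPolar(diff@values, params$sigma)
  out <- list()
  for (reg in stressDefects) {
    sel <- (sm > params$revThreshold) & reg@mask
    if (!any(sel)) next
    lab <- .labelComponents(sel)
    for (l in seq_len(max(lab))) {
      m <- lab == l
      if (sum(m) < params$minAreaCells) next
      out[[length(out) + 1L]] <-
        new("DefectRegion", mask = m, contours = reg@contours,
            kind = "difference_defect")
    }
  }
  out
}

#' Two-stage automatic delineation of reversible perfusion defects
#'
#' The full pipeline: normalizes the stress and rest maps to percent of
#' maximum, delineates stress defects by seeded active contours (stage 1),
#' forms the rest - stress difference image, and extracts strictly
#' reversible sub-regions by smoothing and thresholding inside the stress
#' defects (stage 2).  Downstream extent and SD% use the difference defects.
#'
#' @param stress,rest \linkS4class{PolarMap}s on the same grid (raw counts
#'   or normalized).
#' @param params a [delineationParams()] list.
#' @return List with \code{stressDefects}, \code{differenceDefects} (lists
#'   of \linkS4class{DefectRegion}), and \code{extentPercent}: the
#'   area-weighted percent of the left ventricle covered by the union of
#'   difference defects.
#' @examples
#' g <- makePolarGrid(64, 32)
#' d <- defectSpec(90, 0.7, 40, 0.2, severity = 0.6, reversibility = 1)
#' st <- simulateStudy(g, d, noiseLevel = 0.02, seed = 1)
#' res <- delineate(st$stress, st$rest)
#' res$extentPercent
#' @export
delineate <- function(stress, rest, params = delineationParams()) {
  stopifnot(is(stress, "PolarMap"), is(rest, "PolarMap"))
  if (nTheta(stress) != nTheta(rest) || nRadial(stress) != nRadial(rest))
    stop("stress and rest maps must share one grid")
  stressN <- normalizeUptake(stress)
  restN <- normalizeUptake(rest)
  stressDefects <- delineateStressDefects(stressN, params)
  diff <- differenceMap(stressN, restN)
  differenceDefects <- extractReversible(stressDefects, diff, params)
  list(stressDefects = stressDefects,
       differenceDefects = differenceDefects,
       extentPercent = extentPercent(differenceDefects, stress@grid))
}
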