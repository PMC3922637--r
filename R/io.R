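#' Read a polar map from CSV (+ JSON sidecar)
#'
#' The interchange format is a dense numeric CSV: rows = radial bins from
#' apex (row 1) to base, columns = angular bins from the 3-o'clock position
#' counterclockwise, no header.  A JSON sidecar (same path with extension
#' \code{.json}) records \code{n_theta}, \code{n_r}, \code{phase} and the
#' \code{normalized} flag; when absent, dimensions are inferred from the
#' matrix and \code{phase} falls back to the argument.
#'
#' @param path CSV file path.
#' @param phase fallback phase when no sidecar is present.
#' @return A \linkS4class{PolarMap}.
#' @export
readPolarMap <- function(path, phase = "stress") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty polar-map CSV: ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc != nc[1])) {
    bad <- which(nc != nc[1])[1]
    stop("ragged CSV: row ", bad, " has ", nc[bad], " fields, expected ",
         nc[1])
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  badRow <- which(vapply(vals, anyNA, logical(1)))
  if (length(badRow))
    stop("non-numeric cell in row ", badRow[1], " of ", path)
  m <- do.call(rbind, vals)

  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  normalized <- FALSE
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$n_theta) && meta$n_theta != ncol(m))
      stop("sidecar n_theta (", meta$n_theta, ") does not match CSV columns (",
           ncol(m), ")")
    if (!is.null(meta$n_r) && meta$n_r != nrow(m))
      stop("sidecar n_r (", meta$n_r, ") does not match CSV rows (",
           nrow(m), ")")
    if (!is.null(meta$phase)) phase <- meta$phase
    if (!is.null(meta$normalized)) normalized <- isTRUE(meta$normalized)
  }
  polarMap(m, phase = phase, normalized = normalized)
}

#' Write a polar map to CSV (+ JSON sidecar)
#'
#' @param map a \linkS4class{PolarMap}.
#' @param path output CSV path; the sidecar goes to the same path with
#'   extension \code{.json}.
#' @return Invisibly, \code{path}.
#' @export
writePolarMap <- function(map, path) {
  stopifnot(is(map, "PolarMap"))
  lines <- apply(map@values, 1, function(row)
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ","))
  writeLines(lines, path)
  jsonlite::write_json(
    list(n_theta = nTheta(map), n_r = nRadial(map), phase = map@phase,
         normalized = map@normalized),
    paste0(tools::file_path_sans_ext(path), ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Export a polar map as a grayscale PNG
#'
#' Writes the value matrix (base at the top, apex at the bottom) scaled to
#' \[0, 1\] for quick visual inspection; not a geometric disc rendering.
#'
#' @param map a \linkS4class{PolarMap}.
#' @param path output PNG path.
#' @param masks optional list of logical masks / \linkS4class{DefectRegion}s
#'   overlaid at half intensity.
#' @return Invisibly, \code{path}.
#' @export
writePolarPng <- function(map, path, masks = NULL) {
  v <- map@values
  rng <- range(v)
  img <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  if (!is.null(masks)) {
    u <- Reduce(`|`, lapply(masks, function(r)
      if (is(r, "DefectRegion")) r@mask else r))
    u <- u[rev(seq_len(nrow(u))), , drop = FALSE]
    img <- array(c(img, ifelse(u, 0.5 * img, img),
                   ifelse(u, 0.5 * img, img)), dim = c(dim(img), 3))
  }
  png::writePNG(img, path)
  invisible(path)
}

## Run-length encode one logical row: list of [start, length] runs.
.rleRow <- function(row) {
  r <- rle(as.logical(row))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) c(starts[k], r$lengths[k]))
}

#' Serialize defect regions to JSON
#'
#' Regions are written with per-radial-row run-length encoded masks (1-based
#' \code{[start, length]} runs over angular indices), the contour vertex
#' lists, and the region kind, keeping the files diffable.
#'
#' @param regions list of \linkS4class{DefectRegion}.
#' @param grid the \linkS4class{PolarGrid} the masks live on.
#' @param path output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeRegionsJson <- function(regions, grid, path) {
  payload <- list(
    n_theta = nTheta(grid), n_r = nRadial(grid),
    regions = lapply(regions, function(r) list(
      kind = r@kind,
      mask_rle = lapply(seq_len(nRadial(grid)),
                        function(j) .rleRow(r@mask[j, ])),
      contours = lapply(r@contours, function(ct) list(
        seed = ct@seed, vertices = unname(ct@vertices)))
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read defect regions from JSON
#'
#' @param path JSON path written by [writeRegionsJson()].
#' @return List with \code{grid} (a \linkS4class{PolarGrid}) and
#'   \code{regions} (list of \linkS4class{DefectRegion}; contours are not
#'   reconstructed, masks and kinds are).
#' @export
readRegionsJson <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  grid <- makePolarGrid(p$n_theta, p$n_r)
  regions <- lapply(p$regions, function(r) {
    mask <- matrix(FALSE, p$n_r, p$n_theta)
    for (j in seq_along(r$mask_rle)) {
      for (run in r$mask_rle[[j]]) {
        s <- run[[1]]; len <- run[[2]]
        mask[j, s:(s + len - 1L)] <- TRUE
      }
    }
    new("DefectRegion", mask = mask, contours = list(), kind = r$kind)
  })
  list(grid = grid, regions = regions)
}
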