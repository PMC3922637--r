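#' Accessor generics
#'
#' Small accessor generics for the polar-map containers: grid dimensions,
#' area weights, cell values, map phase, region masks and rater panels.
#' Accessors are the supported way to reach slot contents.
#'
#' @param x An object of the appropriate class.
#' @return The slot contents (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTheta", function(x) standardGeneric("nTheta"))

#' @rdname accessors
#' @export
setGeneric("nRadial", function(x) standardGeneric("nRadial"))

#' @rdname accessors
#' @export
setGeneric("areaWeights", function(x) standardGeneric("areaWeights"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("mapPhase", function(x) standardGeneric("mapPhase"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("polarGrid", function(x) standardGeneric("polarGrid"))

#' @rdname accessors
#' @export
setGeneric("regionMask", function(x) standardGeneric("regionMask"))

#' @rdname accessors
#' @export
setGeneric("regionKind", function(x) standardGeneric("regionKind"))

#' @rdname accessors
#' @export
setGeneric("regionContours", function(x) standardGeneric("regionContours"))

#' @rdname accessors
#' @export
setGeneric("contourVertices", function(x) standardGeneric("contourVertices"))

#' @rdname accessors
#' @export
setGeneric("energyTrace", function(x) standardGeneric("energyTrace"))

#' @rdname accessors
#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname accessors
#' @export
setGeneric("observerIds", function(x) standardGeneric("observerIds"))

#' @rdname accessors
#' @export
setGeneric("nClipped", function(x) standardGeneric("nClipped"))

#' Normalize a polar map to percent of maximum
#'
#' @param x A \linkS4class{PolarMap}.
#' @return A \linkS4class{PolarMap} with values scaled so the maximum is 100.
#' @export
setGeneric("normalizeUptake", function(x) standardGeneric("normalizeUptake"))
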