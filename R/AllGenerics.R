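#' @name conemosaic-accessors
#' @title Accessors for conemosaic classes
#'
#' @description Slot accessors for [ConeField], [ConeTessellation],
#' [DensityMatrix] and [FovealMetrics] objects.  `conePositions()` returns
#' pixel coordinates, `conePositionsUm()` physical micrometre coordinates;
#' `densityValues()` the density grid (cones/mm^2, `NA` where the estimator
#' is undefined) and `validMask()` the corresponding logical mask.
#'
#' @param object an object of the documented class.
#' @return the slot value; see the individual descriptions.
NULL

#' @rdname conemosaic-accessors
#' @export
setGeneric("conePositions", function(object) standardGeneric("conePositions"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("conePositionsUm",
           function(object) standardGeneric("conePositionsUm"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("nCones", function(object) standardGeneric("nCones"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("umPerPixel", function(object) standardGeneric("umPerPixel"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("roiSide", function(object) standardGeneric("roiSide"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("visitNumber", function(object) standardGeneric("visitNumber"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("axialLength", function(object) standardGeneric("axialLength"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("cellAreas", function(object) standardGeneric("cellAreas"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("boundedCells", function(object) standardGeneric("boundedCells"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("cellPolygons", function(object) standardGeneric("cellPolygons"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("densityValues", function(object) standardGeneric("densityValues"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname conemosaic-accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' Convert linear density to angular density
#'
#' Converts cone density from linear retinal units (cones/mm^2) to angular
#' units (cones/deg^2) using the retinal magnification factor implied by the
#' eye's axial length: `angular = linear * (umPerDeg / 1000)^2`.
#'
#' @param x a [DensityMatrix] or a numeric vector/matrix of densities in
#'   cones/mm^2.
#' @param axialLengthMm axial length in mm; for a [DensityMatrix] defaults
#'   to the value stored in the object.
#' @param umPerDeg micrometres per degree of visual angle; computed from
#'   `axialLengthMm` via [umPerDegree()] when not supplied.
#' @return densities in cones/deg^2, same shape as the input.
#' @examples
#' toAngular(187000, axialLengthMm = 24)  # ~15,700 cones/deg^2
#' @export
setGeneric("toAngular",
           function(x, axialLengthMm = NULL, umPerDeg = NULL)
             standardGeneric("toAngular"))
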