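#' Voronoi tessellation with ROI-bounded cell flags
#'
#' Computes the Voronoi diagram of all cones in a field.  Each cone maps to
#' exactly one cell; a cell is flagged *bounded* when it is finite and every
#' vertex lies inside the ROI square.  Only bounded cells enter the density
#' estimator — cones near the ROI edge whose true neighbourhood is partly
#' unobserved are thereby excluded rather than edge-corrected.
#'
#' Cells are built by half-plane clipping against neighbours in order of
#' increasing distance, with a certified stopping rule (a neighbour farther
#' than twice the current maximum vertex distance cannot cut the cell), so
#' the result equals the exact Voronoi diagram.
#'
#' @param field a [ConeField] with at least 4 non-collinear points.
#' @return a [ConeTessellation]; vertices and areas are in micrometres.
#' @examples
#' fld <- generateMosaic(190000, 1e9, 40, jitterSd = 0, seed = 1)
#' tess <- tessellate(fld)
#' sum(boundedCells(tess))
#' @export
tessellate <- function(field) {
  stopifnot(is(field, "ConeField"))
  xy <- conePositionsUm(field)
  n <- nrow(xy)
  if (n < 4L) stop("tessellation needs at least 4 points")
  ctr <- sweep(xy, 2, colMeans(xy))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate (collinear) cone configuration")
  res <- .cpp_voronoi(xy[, 1], xy[, 2], field@roiSideUm, field@roiSideUm)
  new("ConeTessellation", polygons = res$polygons,
      areaUm2 = as.numeric(res$area), bounded = as.logical(res$bounded),
      bbox = res$bbox, coneUm = xy, roiSideUm = field@roiSideUm,
      umPerPixel = field@umPerPixel)
}

#' @rdname conemosaic-accessors
#' @export
setMethod("cellAreas", "ConeTessellation", function(object) object@areaUm2)

#' @rdname conemosaic-accessors
#' @export
setMethod("boundedCells", "ConeTessellation", function(object) object@bounded)

#' @rdname conemosaic-accessors
#' @export
setMethod("cellPolygons", "ConeTessellation",
          function(object) object@polygons)

#' @rdname conemosaic-accessors
#' @export
setMethod("nCones", "ConeTessellation",
          function(object) length(object@polygons))

setMethod("show", "ConeTessellation", function(object) {
  cat(sprintf(
    "ConeTessellation: %d cells (%d bounded) | ROI %g um\n",
    length(object@polygons), sum(object@bounded), object@roiSideUm))
})
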