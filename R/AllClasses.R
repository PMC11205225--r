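#' ConeField: cone coordinates for one ROI
#'
#' Container for the cone centre coordinates of a single foveally centred
#' region of interest (ROI), together with the spatial scale needed to
#' interpret them.  Coordinates are stored in pixels with the origin at the
#' ROI top-left corner, x rightward and y downward; all physical quantities
#' derived from them are reported in micrometres.
#'
#' @slot coords numeric matrix with two columns (x, y), pixel units.
#' @slot umPerPixel micrometres per pixel (> 0).
#' @slot roiSideUm side length of the square ROI in micrometres.
#' @slot subjectId subject identifier.
#' @slot visit visit number (integer).
#' @slot axialLengthMm axial length of the imaged eye in millimetres
#'   (`NA` if unknown; required only for angular-unit densities).
#'
#' @seealso [ConeField()] for the validated constructor.
#' @exportClass ConeField
setClass("ConeField",
  representation(
    coords = "matrix",
    umPerPixel = "numeric",
    roiSideUm = "numeric",
    subjectId = "character",
    visit = "integer",
    axialLengthMm = "numeric"
  )
)

setValidity("ConeField", function(object) {
  msg <- character()
  co <- object@coords
  if (!is.numeric(co) || ncol(co) != 2L)
    msg <- c(msg, "'coords' must be a numeric matrix with two columns")
  if (length(object@umPerPixel) != 1L || !is.finite(object@umPerPixel) ||
      object@umPerPixel <= 0)
    msg <- c(msg, "'umPerPixel' must be a single positive number")
  if (length(object@roiSideUm) != 1L || !is.finite(object@roiSideUm) ||
      object@roiSideUm <= 0)
    msg <- c(msg, "'roiSideUm' must be a single positive number")
  if (length(msg) == 0L && nrow(co) > 0L) {
    if (any(!is.finite(co)))
      msg <- c(msg, "'coords' contains non-finite values")
    else {
      lim <- object@roiSideUm / object@umPerPixel
      tol <- 1e-9 * max(1, lim)
      if (any(co < -tol) || any(co > lim + tol))
        msg <- c(msg, sprintf(
          "coordinates outside the ROI [0, %.6g] px", lim))
      dup <- duplicated(co)
      if (any(dup)) {
        i <- which(dup)[1L]
        j <- which(co[, 1] == co[i, 1] & co[, 2] == co[i, 2])[1L]
        msg <- c(msg, sprintf(
          "duplicate cone coordinates (rows %d and %d are identical); duplicates break the Voronoi tessellation",
          j, i))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ConeTessellation: bounded Voronoi tessellation of a ConeField
#'
#' Voronoi diagram of all cones in an ROI.  Every cone maps to exactly one
#' cell; a cell is flagged `bounded` when it is finite and every vertex lies
#' inside the ROI square.  Vertices and areas are stored in micrometres.
#'
#' @slot polygons list of per-cone vertex matrices (x, y in um).
#' @slot areaUm2 per-cone cell area in um^2.
#' @slot bounded logical flag per cone.
#' @slot bbox n x 4 matrix of cell vertex bounding boxes
#'   (xmin, ymin, xmax, ymax in um).
#' @slot coneUm n x 2 matrix of cone positions in um.
#' @slot roiSideUm ROI side length in um.
#' @slot umPerPixel pixel pitch of the source field (um), used as the
#'   window growth increment by the density engine.
#'
#' @seealso [tessellate()]
#' @exportClass ConeTessellation
setClass("ConeTessellation",
  representation(
    polygons = "list",
    areaUm2 = "numeric",
    bounded = "logical",
    bbox = "matrix",
    coneUm = "matrix",
    roiSideUm = "numeric",
    umPerPixel = "numeric"
  )
)

setValidity("ConeTessellation", function(object) {
  n <- length(object@polygons)
  if (length(object@areaUm2) != n || length(object@bounded) != n ||
      nrow(object@bbox) != n || nrow(object@coneUm) != n)
    return("per-cone slots have inconsistent lengths")
  if (any(object@areaUm2[object@bounded] <= 0))
    return("bounded cells must have positive area")
  TRUE
})

#' DensityMatrix: adaptive-window cone density over an ROI grid
#'
#' Cone density (cones/mm^2) evaluated on a regular grid of points covering
#' the ROI.  Grid cells where the estimator is undefined (the smallest
#' qualifying window would leave the ROI, see [computeDensityMatrix()]) hold
#' `NA` and are excluded from all metrics.
#'
#' Rows index y (downward), columns index x; the physical position of cell
#' `[r, c]` is `originUm + (c(c, r) - 1) * gridUm` micrometres.
#'
#' @slot values density matrix in cones/mm^2, `NA` where invalid.
#' @slot windowSide matched window side length in um, `NA` where invalid.
#' @slot gridUm spacing between grid samples in um
#'   (`umPerPixel * stride`).
#' @slot originUm (x, y) position in um of the centre of cell `[1, 1]`.
#' @slot umPerPixel common pixel scale the field was analysed at (um).
#' @slot stride sampling stride in pixels.
#' @slot k adaptive window target cone count.
#' @slot roiSideUm ROI side length in um.
#' @slot subjectId,visit,axialLengthMm metadata carried from the field.
#'
#' @seealso [computeDensityMatrix()], [findPCD()], [findCDC()]
#' @exportClass DensityMatrix
setClass("DensityMatrix",
  representation(
    values = "matrix",
    windowSide = "matrix",
    gridUm = "numeric",
    originUm = "numeric",
    umPerPixel = "numeric",
    stride = "integer",
    k = "integer",
    roiSideUm = "numeric",
    subjectId = "character",
    visit = "integer",
    axialLengthMm = "numeric"
  )
)

setValidity("DensityMatrix", function(object) {
  msg <- character()
  if (!all(dim(object@values) == dim(object@windowSide)))
    msg <- c(msg, "'values' and 'windowSide' must have identical dimensions")
  if (length(object@gridUm) != 1L || object@gridUm <= 0)
    msg <- c(msg, "'gridUm' must be a single positive number")
  if (length(object@originUm) != 2L)
    msg <- c(msg, "'originUm' must have length 2")
  v <- object@values
  if (any(!is.na(v) & !is.finite(v)))
    msg <- c(msg, "valid density values must be finite")
  if (any(v < 0, na.rm = TRUE))
    msg <- c(msg, "densities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FovealMetrics: summary metrics of one visit's density matrix
#'
#' Peak cone density (PCD), the cone density centroid (CDC), the
#' isodensity contour area and the PCD-CDC offset extracted from a
#' [DensityMatrix].  Angular densities are `NA` when the axial length is
#' unknown.
#'
#' @slot pcdValue,pcdAngular PCD in cones/mm^2 and cones/deg^2.
#' @slot pcdLocation (x, y) of the PCD grid cell centre, um.
#' @slot cdcValue,cdcAngular density at the CDC in cones/mm^2 and
#'   cones/deg^2.
#' @slot cdcLocation (x, y) of the CDC, um.
#' @slot contourAreaUm2 area of the isodensity contour region, um^2.
#' @slot offsetUm Euclidean PCD-CDC distance, um.
#' @slot percentile contour percentile used (default 80).
#' @slot k window target cone count of the source matrix.
#' @slot subjectId,visit metadata.
#'
#' @seealso [fovealMetrics()]
#' @exportClass FovealMetrics
setClass("FovealMetrics",
  representation(
    pcdValue = "numeric",
    pcdAngular = "numeric",
    pcdLocation = "numeric",
    cdcValue = "numeric",
    cdcAngular = "numeric",
    cdcLocation = "numeric",
    contourAreaUm2 = "numeric",
    offsetUm = "numeric",
    percentile = "numeric",
    k = "integer",
    subjectId = "character",
    visit = "integer"
  )
)

setValidity("FovealMetrics", function(object) {
  msg <- character()
  if (is.finite(object@pcdValue) && is.finite(object@cdcValue) &&
      object@pcdValue < object@cdcValue - 1e-9)
    msg <- c(msg, "PCD must be >= density at the CDC (the peak is the maximum)")
  if (is.finite(object@contourAreaUm2) && object@contourAreaUm2 <= 0)
    msg <- c(msg, "'contourAreaUm2' must be positive")
  if (is.finite(object@offsetUm) && object@offsetUm < 0)
    msg <- c(msg, "'offsetUm' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DifferenceMap: CDC-aligned visit2 - visit1 density difference
#'
#' Element-wise density difference of two visits' matrices after translating
#' visit 2 so the cone density centroids coincide, cropped to a square
#' extent centred on the common CDC.  Cells invalid in either input are
#' `NA`.
#'
#' @slot values difference matrix, cones/mm^2 (visit 2 minus visit 1).
#' @slot gridUm grid spacing in um.
#' @slot centerCell (row, col) of the common CDC cell within `values`.
#' @slot subjectId subject identifier.
#'
#' @seealso [differenceMap()], [crossSection()]
#' @exportClass DifferenceMap
setClass("DifferenceMap",
  representation(
    values = "matrix",
    gridUm = "numeric",
    centerCell = "integer",
    subjectId = "character"
  )
)

setValidity("DifferenceMap", function(object) {
  cc <- object@centerCell
  if (length(cc) != 2L || any(cc < 1L) || cc[1L] > nrow(object@values) ||
      cc[2L] > ncol(object@values))
    return("'centerCell' must index a cell of 'values'")
  TRUE
})
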