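#' Construct a ConeField
#'
#' Validated constructor for [ConeField] objects.  Coordinates are pixel
#' positions inside the square ROI (`[0, roiSideUm / umPerPixel]` on both
#' axes, origin top-left, y down).  Exact duplicate points are rejected
#' because they make the Voronoi tessellation degenerate.
#'
#' @param coords two-column matrix or data.frame of (x, y) pixel
#'   coordinates.
#' @param umPerPixel micrometres per pixel.
#' @param roiSideUm ROI side length in micrometres.
#' @param subjectId subject identifier.
#' @param visit visit number.
#' @param axialLengthMm axial length in mm (`NA` if unknown).
#' @return a [ConeField].
#' @examples
#' fld <- ConeField(cbind(c(0, 1, 5), c(0, 2, 5)),
#'                  umPerPixel = 0.5, roiSideUm = 10)
#' nCones(fld)
#' @export
ConeField <- function(coords, umPerPixel, roiSideUm, subjectId = "",
                      visit = 1L, axialLengthMm = NA_real_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  new("ConeField", coords = coords, umPerPixel = as.numeric(umPerPixel),
      roiSideUm = as.numeric(roiSideUm), subjectId = as.character(subjectId),
      visit = as.integer(visit), axialLengthMm = as.numeric(axialLengthMm))
}

#' @rdname conemosaic-accessors
#' @export
setMethod("conePositions", "ConeField", function(object) object@coords)

#' @rdname conemosaic-accessors
#' @export
setMethod("conePositionsUm", "ConeField",
          function(object) object@coords * object@umPerPixel)

#' @rdname conemosaic-accessors
#' @export
setMethod("nCones", "ConeField", function(object) nrow(object@coords))

#' @rdname conemosaic-accessors
#' @export
setMethod("umPerPixel", "ConeField", function(object) object@umPerPixel)

#' @rdname conemosaic-accessors
#' @export
setMethod("roiSide", "ConeField", function(object) object@roiSideUm)

#' @rdname conemosaic-accessors
#' @export
setMethod("subjectId", "ConeField", function(object) object@subjectId)

#' @rdname conemosaic-accessors
#' @export
setMethod("visitNumber", "ConeField", function(object) object@visit)

#' @rdname conemosaic-accessors
#' @export
setMethod("axialLength", "ConeField", function(object) object@axialLengthMm)

setMethod("show", "ConeField", function(object) {
  cat(sprintf(
    "ConeField: %d cones | ROI %g x %g um | %g um/px | subject '%s' visit %d\n",
    nrow(object@coords), object@roiSideUm, object@roiSideUm,
    object@umPerPixel, object@subjectId, object@visit))
  if (!is.na(object@axialLengthMm))
    cat(sprintf("  axial length %.2f mm\n", object@axialLengthMm))
})

#' Rescale a ConeField to a common pixel scale
#'
#' Multiplies pixel coordinates by `umPerPixel / targetUmPerPixel` so that
#' every field in a study shares one pixel pitch before density analysis.
#' Physical cone positions (in micrometres) are unchanged.
#'
#' @param field a [ConeField].
#' @param targetUmPerPixel the common scale in micrometres per pixel
#'   (default 0.25).
#' @return a [ConeField] at the target scale.
#' @examples
#' fld <- ConeField(cbind(10, 10), umPerPixel = 1, roiSideUm = 50)
#' conePositions(rescaleToCommon(fld, 0.5))  # (20, 20) px
#' @export
rescaleToCommon <- function(field, targetUmPerPixel = 0.25) {
  stopifnot(is(field, "ConeField"))
  if (!is.numeric(targetUmPerPixel) || length(targetUmPerPixel) != 1L ||
      !is.finite(targetUmPerPixel) || targetUmPerPixel <= 0)
    stop("'targetUmPerPixel' must be a single positive number")
  if (targetUmPerPixel == field@umPerPixel) return(field)
  ratio <- field@umPerPixel / targetUmPerPixel
  ConeField(field@coords * ratio, targetUmPerPixel, field@roiSideUm,
            field@subjectId, field@visit, field@axialLengthMm)
}

#' Crop a ConeField to a centred square sub-ROI
#'
#' Keeps the cones inside a square of side `sideUm` centred at `centerUm`
#' (default: the ROI centre) and re-origins coordinates to the crop's
#' top-left corner.  Used to extract a common analysis window when visits
#' were acquired with different ROI sizes.
#'
#' @param field a [ConeField].
#' @param sideUm side length of the crop in micrometres.
#' @param centerUm (x, y) centre of the crop in micrometres; default ROI
#'   centre.
#' @return a [ConeField] with `roiSideUm = sideUm`.
#' @export
cropConeField <- function(field, sideUm, centerUm = NULL) {
  stopifnot(is(field, "ConeField"))
  if (sideUm <= 0 || sideUm > field@roiSideUm + 1e-9)
    stop("'sideUm' must be positive and no larger than the ROI side")
  if (is.null(centerUm)) centerUm <- rep(field@roiSideUm / 2, 2L)
  offUm <- centerUm - sideUm / 2
  if (any(offUm < -1e-9) || any(offUm + sideUm > field@roiSideUm + 1e-9))
    stop("crop window extends beyond the ROI")
  offPx <- offUm / field@umPerPixel
  sidePx <- sideUm / field@umPerPixel
  co <- field@coords
  keep <- co[, 1] >= offPx[1] & co[, 1] <= offPx[1] + sidePx &
          co[, 2] >= offPx[2] & co[, 2] <= offPx[2] + sidePx
  co <- co[keep, , drop = FALSE]
  co[, 1] <- co[, 1] - offPx[1]
  co[, 2] <- co[, 2] - offPx[2]
  ConeField(co, field@umPerPixel, sideUm, field@subjectId, field@visit,
            field@axialLengthMm)
}
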