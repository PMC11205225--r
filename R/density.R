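#' Adaptive-window cone density at arbitrary points
#'
#' Evaluates the bounded-Voronoi adaptive-window density estimator at given
#' points.  At each point the smallest axis-aligned square window — grown in
#' whole-pixel increments of the field's pixel grid — whose interior
#' strictly contains the Voronoi cells of at least `k` cones is found;
#' the density is the number of contained cells divided by their summed
#' Voronoi area (cones/mm^2).  The result is *missing* (`NA`) when the
#' required window would extend beyond the ROI, or when fewer than `k`
#' bounded cells exist at all.
#'
#' @param field a [ConeField] (used for scale and ROI geometry).
#' @param tess the field's [ConeTessellation]; computed if `NULL`.
#' @param pointsUm two-column matrix of query points in um.
#' @param k window target cone count (default 150; must be >= 3).
#' @return data.frame with columns `density` (cones/mm^2),
#'   `window_side_um` and `count` (cones contributing at the accepted
#'   window size, which may slightly exceed `k`).
#' @seealso [computeDensityMatrix()] for evaluation over the full ROI grid.
#' @export
densityAt <- function(field, pointsUm, k = 150L, tess = NULL) {
  stopifnot(is(field, "ConeField"))
  if (k < 3L) stop("'k' must be at least 3")
  if (is.null(tess)) tess <- tessellate(field)
  pointsUm <- matrix(as.numeric(pointsUm), ncol = 2L)
  b <- tess@bounded
  res <- .cpp_density_at(tess@bbox[b, , drop = FALSE],
                         tess@coneUm[b, 1], tess@coneUm[b, 2],
                         tess@areaUm2[b],
                         pointsUm[, 1], pointsUm[, 2],
                         as.integer(k), field@umPerPixel,
                         field@roiSideUm, field@roiSideUm)
  data.frame(density = res$density, window_side_um = res$window_side,
             count = res$count)
}

#' Compute the density matrix of an ROI
#'
#' Runs the adaptive-window estimator of [densityAt()] on the regular pixel
#' grid of the field (every `stride`-th pixel in x and y), producing the
#' density matrix from which the foveal metrics are extracted.  Grid cells
#' whose smallest qualifying window would cross the ROI boundary are
#' missing (`NA`); the high-density foveal centre always lies in the valid
#' interior.
#'
#' @param field a [ConeField], already rescaled to the study's common pixel
#'   scale (see [rescaleToCommon()]).
#' @param k window target cone count (default 150).
#' @param stride grid sampling stride in pixels (default 1 = every pixel);
#'   coarser strides subsample the same grid nodes.
#' @param tess optional precomputed [ConeTessellation].
#' @return a [DensityMatrix].
#' @export
computeDensityMatrix <- function(field, k = 150L, stride = 1L, tess = NULL) {
  stopifnot(is(field, "ConeField"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("'stride' must be a positive integer")
  if (nCones(field) < k)
    stop(sprintf("field has %d cones but k = %d; density analysis needs at least k cones",
                 nCones(field), k))
  if (is.null(tess)) tess <- tessellate(field)
  s <- field@umPerPixel
  npx <- floor(field@roiSideUm / s + 1e-9)
  idx <- seq.int(0L, npx - 1L, by = stride)
  centers <- (idx + 0.5) * s
  grid <- cbind(rep(centers, times = length(centers)),
                rep(centers, each = length(centers)))
  b <- tess@bounded
  res <- .cpp_density_at(tess@bbox[b, , drop = FALSE],
                         tess@coneUm[b, 1], tess@coneUm[b, 2],
                         tess@areaUm2[b],
                         grid[, 1], grid[, 2],
                         as.integer(k), s,
                         field@roiSideUm, field@roiSideUm)
  nx <- length(centers)
  vals <- matrix(res$density, nrow = nx, ncol = nx, byrow = TRUE)
  wins <- matrix(res$window_side, nrow = nx, ncol = nx, byrow = TRUE)
  new("DensityMatrix", values = vals, windowSide = wins,
      gridUm = s * stride, originUm = c(centers[1L], centers[1L]),
      umPerPixel = s, stride = stride, k = as.integer(k),
      roiSideUm = field@roiSideUm, subjectId = field@subjectId,
      visit = field@visit, axialLengthMm = field@axialLengthMm)
}

#' @rdname conemosaic-accessors
#' @export
setMethod("densityValues", "DensityMatrix", function(object) object@values)

#' @rdname conemosaic-accessors
#' @export
setMethod("validMask", "DensityMatrix",
          function(object) !is.na(object@values))

#' @rdname conemosaic-accessors
#' @export
setMethod("gridSpacing", "DensityMatrix", function(object) object@gridUm)

#' @rdname conemosaic-accessors
#' @export
setMethod("gridOrigin", "DensityMatrix", function(object) object@originUm)

#' @rdname conemosaic-accessors
#' @export
setMethod("subjectId", "DensityMatrix", function(object) object@subjectId)

#' @rdname conemosaic-accessors
#' @export
setMethod("visitNumber", "DensityMatrix", function(object) object@visit)

#' @rdname conemosaic-accessors
#' @export
setMethod("axialLength", "DensityMatrix",
          function(object) object@axialLengthMm)

setMethod("show", "DensityMatrix", function(object) {
  v <- object@values
  cat(sprintf(
    "DensityMatrix: %d x %d grid (%.3g um spacing) | k = %d | %d%% valid\n",
    nrow(v), ncol(v), object@gridUm, object@k,
    round(100 * mean(!is.na(v)))))
  if (any(!is.na(v)))
    cat(sprintf("  density range %.4g - %.4g cones/mm^2\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

# x/y positions (um) of the matrix columns / rows
.gridX <- function(dm) dm@originUm[1L] + (seq_len(ncol(dm@values)) - 1L) * dm@gridUm
.gridY <- function(dm) dm@originUm[2L] + (seq_len(nrow(dm@values)) - 1L) * dm@gridUm

#' @rdname toAngular
#' @export
setMethod("toAngular", "DensityMatrix",
  function(x, axialLengthMm = NULL, umPerDeg = NULL) {
    if (is.null(umPerDeg)) {
      if (is.null(axialLengthMm)) axialLengthMm <- x@axialLengthMm
      if (is.na(axialLengthMm))
        stop("axial length unknown: supply 'axialLengthMm' or 'umPerDeg' ",
             "for the angular conversion")
      umPerDeg <- umPerDegree(axialLengthMm)
    }
    x@values * (umPerDeg / 1000)^2
  })

#' @rdname toAngular
#' @export
setMethod("toAngular", "ANY",
  function(x, axialLengthMm = NULL, umPerDeg = NULL) {
    if (!is.numeric(x)) stop("'x' must be numeric or a DensityMatrix")
    if (is.null(umPerDeg)) {
      if (is.null(axialLengthMm))
        stop("axial length unknown: supply 'axialLengthMm' or 'umPerDeg' ",
             "for the angular conversion")
      umPerDeg <- umPerDegree(axialLengthMm)
    }
    x * (umPerDeg / 1000)^2
  })
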