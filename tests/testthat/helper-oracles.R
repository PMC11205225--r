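# Shared fixtures and independent oracles.

# analytic density of a hexagonal lattice with spacing s (um) in cones/mm^2
hexDensity <- function(s) 2 / (sqrt(3) * s^2) * 1e6

# hexagonal lattice spacing for a target density (cones/mm^2)
hexSpacing <- function(density) sqrt(2 / (sqrt(3) * density * 1e-6))

# Exhaustive window-search oracle for the adaptive-window density estimator.
# Works from the Voronoi polygon vertices directly: for each candidate
# whole-pixel window side in increasing order, count the cells whose
# vertices all lie strictly inside the window, and accept the first side
# with >= k of them.  Returns c(density, window_side_um) or NAs.
oracleDensityAt <- function(field, tess, q, k = 150) {
  px <- umPerPixel(field)
  roi <- roiSide(field)
  idx <- which(boundedCells(tess))
  polys <- cellPolygons(tess)
  areas <- cellAreas(tess)
  req <- vapply(idx, function(i) {
    v <- polys[[i]]
    max(abs(v[, 1] - q[1]), abs(v[, 2] - q[2]))
  }, numeric(1))
  maxHalf <- min(q[1], roi - q[1], q[2], roi - q[2])
  for (L in seq_len(floor(2 * maxHalf / px + 1e-9))) {
    half <- L * px / 2
    sel <- req < half
    if (sum(sel) >= k)
      return(c(density = sum(sel) / sum(areas[idx][sel]) * 1e6,
               side = L * px))
  }
  c(density = NA_real_, side = NA_real_)
}

# small DensityMatrix built directly from a value matrix (grid spacing 1 um
# unless stated); for metric-level tests that need no density engine
makeDM <- function(values, gridUm = 1, originUm = c(gridUm / 2, gridUm / 2),
                   axialLengthMm = NA_real_) {
  methods::new("DensityMatrix", values = values,
               windowSide = array(NA_real_, dim(values)),
               gridUm = gridUm, originUm = originUm, umPerPixel = gridUm,
               stride = 1L, k = 150L,
               roiSideUm = max(dim(values)) * gridUm,
               subjectId = "fixture", visit = 1L,
               axialLengthMm = axialLengthMm)
}

# radially symmetric single-peak value matrix (peak at the centre cell)
peakMatrix <- function(n = 21, peak = 100, scale = 8) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(r, c)
    peak * exp(-sqrt((r - ctr)^2 + (c - ctr)^2) / scale))
}

# a DifferenceMap built directly from a value matrix
makeDiff <- function(values, gridUm = 1,
                     centerCell = as.integer(ceiling(dim(values) / 2))) {
  methods::new("DifferenceMap", values = values, gridUm = gridUm,
               centerCell = centerCell, subjectId = "fixture")
}

# zero-perturbation revisit settings for null cohorts
nullRevisit <- list(translationSd = 0, scaleErrorSd = 0, extraJitterSd = 0,
                    missRate = 0, falseRate = 0)
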