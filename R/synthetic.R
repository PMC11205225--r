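# Synthetic foveal mosaics with analytically known density.
#
# The generator lays down a regular hexagonal lattice of density
# `peakDensity` in a reference plane and warps it radially so the realised
# local density is D(r) = peakDensity * exp(-r / falloffScale) around the
# peak.  The warp T: r0 -> r conserves points,
#   r0(r)^2 / 2 = integral_0^r exp(-u/lambda) u du
#               = lambda^2 * (1 - exp(-r/lambda) (1 + r/lambda)),
# so the analytic profile is exact (up to packing jitter), giving every
# downstream density estimate a closed-form oracle.

# 1 - exp(-u)(1+u), stable for small u
.omexp1p <- function(u) {
  small <- u < 1e-3
  out <- numeric(length(u))
  us <- u[small]
  out[small] <- us^2 / 2 - us^3 / 3 + us^4 / 8
  ul <- u[!small]
  out[!small] <- 1 - exp(-ul) * (1 + ul)
  out
}

# reference-plane radius corresponding to true radius r
.r0_of_r <- function(r, lambda) {
  sqrt(2) * lambda * sqrt(.omexp1p(r / lambda))
}

#' Generate a synthetic foveal cone mosaic
#'
#' Produces a quasi-hexagonally packed cone mosaic over a square ROI with a
#' radially decaying density field
#' `D(r) = peakDensity * exp(-r / falloffScale)` (cones/mm^2) around a peak
#' at the ROI centre plus `peakOffsetUm`.  Local packing is a hexagonal
#' lattice with spacing `s(r) = sqrt(2 / (sqrt(3) * D(r)))` plus isotropic
#' Gaussian position jitter, so both the local density and the local
#' spacing have closed forms for parameter-recovery tests.
#'
#' @param peakDensity density at the peak, cones/mm^2.
#' @param falloffScale radial e-folding distance of the density, um.  Use a
#'   very large value (e.g. `1e9`) for an effectively uniform mosaic.
#' @param roiSideUm ROI side length, um.
#' @param jitterSd isotropic Gaussian position jitter SD, um.
#' @param peakOffsetUm (x, y) offset of the density peak from the ROI
#'   centre, um.
#' @param umPerPixel pixel scale the coordinates are expressed in.
#' @param seed integer seed; the mosaic is bit-reproducible given the seed.
#' @param subjectId,visit,axialLengthMm metadata for the output field.
#' @return a [ConeField].
#' @examples
#' fld <- generateMosaic(190000, 1e9, 300, jitterSd = 0, seed = 1)
#' nCones(fld) / (0.3^2)  # ~190,000 cones/mm^2
#' @export
generateMosaic <- function(peakDensity, falloffScale, roiSideUm,
                           jitterSd = 0.35, peakOffsetUm = c(0, 0),
                           umPerPixel = 0.45, seed = NULL,
                           subjectId = "synthetic", visit = 1L,
                           axialLengthMm = NA_real_) {
  if (peakDensity <= 0) stop("'peakDensity' must be positive")
  if (falloffScale <= 0) stop("'falloffScale' must be positive")
  if (roiSideUm <= 0) stop("'roiSideUm' must be positive")
  if (jitterSd < 0) stop("'jitterSd' must be non-negative")
  withSeed(seed, {
    Pum <- peakDensity * 1e-6                    # cones per um^2 at the peak
    s0 <- sqrt(2 / (sqrt(3) * Pum))              # hex spacing at the peak
    ctr <- roiSideUm / 2 + peakOffsetUm

    # farthest true radius the lattice must reach (ROI corner + margins)
    corners <- rbind(c(0, 0), c(roiSideUm, 0), c(0, roiSideUm),
                     c(roiSideUm, roiSideUm))
    rmax <- max(sqrt(rowSums(sweep(corners, 2, ctr)^2))) +
      4 * jitterSd + 2 * s0
    r0max <- .r0_of_r(rmax, falloffScale)

    # hexagonal lattice covering the reference disk of radius r0max
    a2y <- s0 * sqrt(3) / 2
    jmax <- ceiling(r0max / a2y) + 1L
    pts <- vector("list", 2L * jmax + 1L)
    for (j in -jmax:jmax) {
      yy <- j * a2y
      half <- sqrt(max(0, r0max^2 - yy^2))
      xoff <- (j %% 2) * s0 / 2
      i0 <- ceiling((-half - xoff) / s0)
      i1 <- floor((half - xoff) / s0)
      if (i1 < i0) next
      xx <- (i0:i1) * s0 + xoff
      pts[[j + jmax + 1L]] <- cbind(xx, rep(yy, length(xx)))
    }
    lat <- do.call(rbind, pts)
    r0 <- sqrt(rowSums(lat^2))
    keep <- r0 <= r0max
    lat <- lat[keep, , drop = FALSE]
    r0 <- r0[keep]

    # invert the radial warp with a monotone spline
    rg <- seq(0, rmax * 1.05, length.out = 4096L)
    r0g <- .r0_of_r(rg, falloffScale)
    rinv <- splinefun(r0g, rg, method = "hyman")
    stretch <- ifelse(r0 > 0, rinv(r0) / r0, 1)

    xy <- lat * stretch
    xy[, 1] <- xy[, 1] + ctr[1]
    xy[, 2] <- xy[, 2] + ctr[2]
    if (jitterSd > 0)
      xy <- xy + matrix(rnorm(2L * nrow(xy), 0, jitterSd), ncol = 2L)

    inside <- xy[, 1] >= 0 & xy[, 1] <= roiSideUm &
              xy[, 2] >= 0 & xy[, 2] <= roiSideUm
    xy <- xy[inside, , drop = FALSE]
    if (nrow(xy) < 200L)
      stop(sprintf(
        "parameters produce only %d cones (< 200); downstream 150-cone windows would be undefined",
        nrow(xy)))
    ConeField(xy / umPerPixel, umPerPixel, roiSideUm, subjectId, visit,
              axialLengthMm)
  })
}

#' Simulate a revisit of a cone mosaic
#'
#' Applies the intervisit variability model to a field: a rigid translation,
#' a multiplicative scale error about the ROI centre (emulating an image
#' scale calibration error), extra position jitter (re-marking noise),
#' random cone misses, and spurious false detections placed uniformly over
#' the ROI.  With all perturbations zero the output is exactly the input.
#'
#' @param field a [ConeField].
#' @param translationUm rigid (dx, dy) shift in um.
#' @param scaleError multiplicative coordinate factor (> 0) about the ROI
#'   centre; a factor `c` scales local density by `1 / c^2`.
#' @param extraJitterSd additional Gaussian position jitter SD, um.
#' @param missRate probability in `[0, 1)` that each cone is dropped.
#' @param falseRate spurious points are added as
#'   `Poisson(falseRate * nCones)` uniform points.
#' @param seed integer seed.
#' @param visit visit number for the output field.
#' @return a [ConeField] on the same ROI.
#' @export
simulateRevisit <- function(field, translationUm = c(0, 0), scaleError = 1,
                            extraJitterSd = 0, missRate = 0, falseRate = 0,
                            seed = NULL, visit = visitNumber(field)) {
  stopifnot(is(field, "ConeField"))
  if (nCones(field) == 0L) stop("'field' has no cones")
  if (scaleError <= 0) stop("'scaleError' must be positive")
  if (missRate < 0 || missRate >= 1) stop("'missRate' must be in [0, 1)")
  if (falseRate < 0 || falseRate >= 1) stop("'falseRate' must be in [0, 1)")
  # all-zero perturbations: exact identity on coordinates
  if (all(translationUm == 0) && scaleError == 1 && extraJitterSd == 0 &&
      missRate == 0 && falseRate == 0) {
    out <- field
    out@visit <- as.integer(visit)
    return(out)
  }
  withSeed(seed, {
    side <- field@roiSideUm
    xy <- conePositionsUm(field)
    n0 <- nrow(xy)
    if (any(translationUm != 0))
      xy <- sweep(xy, 2, translationUm, "+")
    if (scaleError != 1) {
      ctr <- side / 2
      xy <- (xy - ctr) * scaleError + ctr
    }
    if (extraJitterSd > 0)
      xy <- xy + matrix(rnorm(2L * nrow(xy), 0, extraJitterSd), ncol = 2L)
    if (missRate > 0)
      xy <- xy[runif(nrow(xy)) >= missRate, , drop = FALSE]
    if (falseRate > 0) {
      nf <- rpois(1L, falseRate * n0)
      if (nf > 0)
        xy <- rbind(xy, matrix(runif(2L * nf, 0, side), ncol = 2L))
    }
    inside <- xy[, 1] >= 0 & xy[, 1] <= side &
              xy[, 2] >= 0 & xy[, 2] <= side
    xy <- xy[inside, , drop = FALSE]
    ConeField(xy / field@umPerPixel, field@umPerPixel, side,
              field@subjectId, visit, field@axialLengthMm)
  })
}

#' Generate a synthetic two-visit cohort
#'
#' Emulates a longitudinal reproducibility study: for each subject a master
#' foveal mosaic is generated over the visit-2 ROI (500 um square by
#' default), visit 1 is its centred 300-um crop (crops use
#' [cropConeField()], the same operation the cohort pipeline applies to
#' visit 2, so a zero-perturbation revisit reproduces visit 1 exactly), and
#' visit 2 is a perturbed revisit of the master field.  Per-subject mosaic
#' parameters are drawn uniformly from `mosaicRanges`; axial length and
#' intervisit interval are drawn from truncated normal models of a healthy
#' adult cohort.  The per-subject pixel scale is derived from axial length
#' through [umPerDegree()] times a fixed system scale, so rescaling to a
#' common grid is a real step.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param mosaicRanges list with elements `peakDensity` (range, cones/mm^2),
#'   `falloffScale` (range, um), `jitterSd` (single value, um) and
#'   `peakOffsetMax` (max peak offset radius, um).
#' @param revisit list of intervisit variability parameters.
#'   `translationSd` (um) and `scaleErrorSd` (log-scale SD of the
#'   multiplicative factor) are visit-2 acquisition effects (fixation
#'   offset, scale calibration error); `extraJitterSd` (um), `missRate`
#'   and `falseRate` model the cone-marking noise and are applied
#'   independently to *both* visits, as both visits' coordinates come from
#'   the same marking process.  Set all to zero for a null cohort (then
#'   visit 2 centre-crops back to exactly visit 1).
#' @param roiSideVisit1,roiSideVisit2 ROI side lengths in um.
#' @param degPerPixel system angular pixel scale used to derive each
#'   subject's um/px from axial length.
#' @param seed integer seed; the whole cohort is reproducible given it.
#' @return an object of class `"ConeCohort"`: a list of subjects, each with
#'   elements `subjectId`, `visit1`, `visit2` ([ConeField]s),
#'   `axialLengthMm`, `intervalYears` and `truth` (the generating
#'   parameters).
#' @examples
#' coh <- generateCohort(2, seed = 7,
#'                       revisit = list(translationSd = 0, scaleErrorSd = 0,
#'                                      extraJitterSd = 0, missRate = 0,
#'                                      falseRate = 0))
#' length(coh)
#' @export
generateCohort <- function(nSubjects = 19L,
                           mosaicRanges = list(peakDensity = c(175e3, 240e3),
                                               falloffScale = c(90, 140),
                                               jitterSd = 0.35,
                                               peakOffsetMax = 15),
                           revisit = list(translationSd = 15,
                                          scaleErrorSd = 0.01,
                                          extraJitterSd = 0.3,
                                          missRate = 0.03,
                                          falseRate = 0.03),
                           roiSideVisit1 = 300, roiSideVisit2 = 500,
                           degPerPixel = 0.45 / 289.7, seed = NULL) {
  if (nSubjects < 2L) stop("'nSubjects' must be at least 2")
  for (nm in c("peakDensity", "falloffScale")) {
    rg <- mosaicRanges[[nm]]
    if (is.null(rg) || length(rg) != 2L || any(!is.finite(rg)) ||
        rg[2] < rg[1])
      stop("invalid or empty range for '", nm, "'")
  }
  withSeed(seed, {
    subjects <- vector("list", nSubjects)
    for (i in seq_len(nSubjects)) {
      id <- sprintf("SYN_%03d", i)
      P <- runif(1, mosaicRanges$peakDensity[1], mosaicRanges$peakDensity[2])
      lam <- runif(1, mosaicRanges$falloffScale[1],
                   mosaicRanges$falloffScale[2])
      th <- runif(1, 0, 2 * pi)
      rr <- runif(1, 0, mosaicRanges$peakOffsetMax %||% 0)
      off <- rr * c(cos(th), sin(th))
      al <- min(27, max(21, rnorm(1, 23.91, 0.96)))
      interval <- min(4.28, max(2.48, rnorm(1, 3.20, 0.51)))
      ump <- degPerPixel * umPerDegree(al)

      master <- generateMosaic(P, lam, roiSideVisit2,
                               jitterSd = mosaicRanges$jitterSd %||% 0.35,
                               peakOffsetUm = off, umPerPixel = ump,
                               subjectId = id, visit = 1L,
                               axialLengthMm = al)
      # marking noise (re-identification jitter, misses, false detections)
      # affects both visits independently; translation and scale error are
      # visit-2 acquisition effects
      v1 <- simulateRevisit(cropConeField(master, roiSideVisit1),
                            extraJitterSd = revisit$extraJitterSd %||% 0,
                            missRate = revisit$missRate %||% 0,
                            falseRate = revisit$falseRate %||% 0,
                            visit = 1L)
      tr <- rnorm(2, 0, revisit$translationSd %||% 0)
      sc <- exp(rnorm(1, 0, revisit$scaleErrorSd %||% 0))
      if ((revisit$translationSd %||% 0) == 0) tr <- c(0, 0)
      if ((revisit$scaleErrorSd %||% 0) == 0) sc <- 1
      v2 <- simulateRevisit(master, translationUm = tr, scaleError = sc,
                            extraJitterSd = revisit$extraJitterSd %||% 0,
                            missRate = revisit$missRate %||% 0,
                            falseRate = revisit$falseRate %||% 0,
                            visit = 2L)
      subjects[[i]] <- list(
        subjectId = id, visit1 = v1, visit2 = v2, axialLengthMm = al,
        intervalYears = interval,
        truth = list(peakDensity = P, falloffScale = lam, peakOffsetUm = off,
                     translationUm = tr, scaleError = sc))
    }
    structure(subjects, class = "ConeCohort")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ConeCohort <- function(x, ...) {
  cat(sprintf("ConeCohort: %d subjects, two visits each\n", length(x)))
  invisible(x)
}
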