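#' Run the full two-visit cohort pipeline
#'
#' Drives the complete analysis for a cohort of subjects imaged at two
#' visits: per visit, cones are cropped to a common square analysis window,
#' rescaled to the common pixel scale, tessellated, converted to a density
#' matrix and summarised as [FovealMetrics]; per subject, the two matrices
#' are CDC-aligned into a difference map with horizontal and vertical
#' cross-section profiles; across subjects, every metric gets the
#' reproducibility statistics (Shapiro-Wilk on the differences, paired t,
#' Pearson with Fisher-z CI, Bland-Altman, percent change, and the
#' correlation of intervisit interval with absolute differences).
#'
#' Both visits are analysed on the same `analysisSideUm` window (centred
#' crop; visit 2's larger acquisition ROI exists to tolerate fixation
#' offsets between visits, and its central crop still contains the fovea).
#' A common window keeps the rank-percentile contour area comparable
#' across visits.  Difference maps are built from these same matrices, so a
#' subject whose two visits are identical yields an exactly zero map.
#'
#' @param cohort a `"ConeCohort"` from [generateCohort()], or any list of
#'   subjects with elements `subjectId`, `visit1`, `visit2`
#'   ([ConeField]s), and optionally `axialLengthMm` and `intervalYears`.
#'   Subjects missing a visit are excluded with a warning.
#' @param k adaptive window target cone count.
#' @param commonScale common pixel scale all fields are rescaled to,
#'   um/pixel.
#' @param stride density grid stride in pixels of the common scale.
#' @param pct contour percentile.
#' @param binUm cross-section bin width, um.
#' @param analysisSideUm side of the common analysis window, um.
#' @param computeProfiles logical; skip difference maps and profiles for
#'   speed when `FALSE`.
#' @param verbose print per-subject progress.
#' @return object of class `"cohortResult"`: list with `table`
#'   (per-subject metric data.frame), `stats` (per-metric list of
#'   `shapiro`, `pairedT`, `pearson`, `blandAltman`, `percentChange`,
#'   `intervalCor`), `profiles` (`horizontal`/`vertical` composites and
#'   `perSubject`), `report` (the table rounded to 3 significant digits)
#'   and `config`.
#' @export
runCohort <- function(cohort, k = 150L, commonScale = 0.25, stride = 10L,
                      pct = 80, binUm = 5, analysisSideUm = 300,
                      computeProfiles = TRUE, verbose = FALSE) {
  ok <- vapply(cohort, function(s)
    is(s$visit1, "ConeField") && is(s$visit2, "ConeField"), logical(1))
  if (any(!ok)) {
    bad <- vapply(cohort[!ok], function(s)
      if (is.null(s$subjectId)) "<unnamed>" else s$subjectId, character(1))
    warning("excluding subjects missing a visit: ",
            paste(bad, collapse = ", "))
    cohort <- cohort[ok]
  }
  if (length(cohort) < 2L) stop("cohort has fewer than 2 complete subjects")

  prepVisit <- function(fld, al) {
    if (!is.na(al)) fld@axialLengthMm <- al
    if (fld@roiSideUm > analysisSideUm + 1e-9)
      fld <- cropConeField(fld, analysisSideUm)
    rescaleToCommon(fld, commonScale)
  }

  rows <- list()
  dms <- list()
  hprofiles <- list()
  vprofiles <- list()
  for (s in cohort) {
    al <- if (is.null(s$axialLengthMm)) NA_real_ else s$axialLengthMm
    f1 <- prepVisit(s$visit1, al)
    f2 <- prepVisit(s$visit2, al)
    dm1 <- computeDensityMatrix(f1, k = k, stride = stride)
    dm2 <- computeDensityMatrix(f2, k = k, stride = stride)
    m1 <- fovealMetrics(dm1, pct)
    m2 <- fovealMetrics(dm2, pct)
    if (verbose)
      message(sprintf("%s: PCD %.0f / %.0f cones/mm^2",
                      s$subjectId, m1@pcdValue, m2@pcdValue))
    rows[[s$subjectId]] <- data.frame(
      subject = s$subjectId,
      pcd_mm2_v1 = m1@pcdValue, pcd_mm2_v2 = m2@pcdValue,
      pcd_deg2_v1 = m1@pcdAngular, pcd_deg2_v2 = m2@pcdAngular,
      cdc_mm2_v1 = m1@cdcValue, cdc_mm2_v2 = m2@cdcValue,
      cdc_deg2_v1 = m1@cdcAngular, cdc_deg2_v2 = m2@cdcAngular,
      area_um2_v1 = m1@contourAreaUm2, area_um2_v2 = m2@contourAreaUm2,
      offset_um_v1 = m1@offsetUm, offset_um_v2 = m2@offsetUm,
      axial_length_mm = al,
      interval_years = if (is.null(s$intervalYears)) NA_real_
                       else s$intervalYears)
    if (computeProfiles) {
      dmap <- suppressWarnings(differenceMap(dm1, dm2,
                                             extentUm = analysisSideUm, pct))
      hprofiles[[s$subjectId]] <- crossSection(dmap, "horizontal", binUm)
      vprofiles[[s$subjectId]] <- crossSection(dmap, "vertical", binUm)
      dms[[s$subjectId]] <- dmap
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  metricCols <- c(pcd_mm2 = "pcd_mm2", pcd_deg2 = "pcd_deg2",
                  cdc_mm2 = "cdc_mm2", cdc_deg2 = "cdc_deg2",
                  area_um2 = "area_um2", offset_um = "offset_um")
  tryNA <- function(expr) tryCatch(expr, error = function(e) NULL)
  stats <- lapply(metricCols, function(mc) {
    v1 <- tab[[paste0(mc, "_v1")]]
    v2 <- tab[[paste0(mc, "_v2")]]
    if (all(is.na(v1))) return(NULL)        # angular without axial length
    d <- v2 - v1
    iv <- tab$interval_years
    list(
      shapiro = tryNA(shapiroWilkTest(d)),
      pairedT = tryNA(pairedT(v1, v2)),
      pearson = tryNA(pearsonWithCI(v1, v2)),
      blandAltman = tryNA(blandAltman(v1, v2)),
      percentChange = if (mc != "offset_um") percentChange(v1, v2) else NULL,
      intervalCor = if (all(is.finite(iv))) tryNA(pearsonWithCI(iv, abs(d)))
                    else NULL)
  })

  profiles <- NULL
  if (computeProfiles) {
    profiles <- list(horizontal = compositeProfile(hprofiles),
                     vertical = compositeProfile(vprofiles),
                     perSubject = list(horizontal = hprofiles,
                                       vertical = vprofiles))
  }

  report <- tab
  for (cn in setdiff(names(report), "subject"))
    report[[cn]] <- roundSig(report[[cn]], 3)

  structure(list(table = tab, stats = stats, profiles = profiles,
                 differenceMaps = if (computeProfiles) dms else NULL,
                 report = report,
                 config = list(k = k, commonScale = commonScale,
                               stride = stride, pct = pct, binUm = binUm,
                               analysisSideUm = analysisSideUm)),
            class = "cohortResult")
}

#' @export
print.cohortResult <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("Cohort reproducibility result: %d subjects\n", n))
  fmt <- function(v) format(roundSig(mean(v), 3), big.mark = ",")
  cat(sprintf("  mean PCD  %s (v1) / %s (v2) cones/mm^2\n",
              fmt(x$table$pcd_mm2_v1), fmt(x$table$pcd_mm2_v2)))
  cat(sprintf("  mean CDC  %s (v1) / %s (v2) cones/mm^2\n",
              fmt(x$table$cdc_mm2_v1), fmt(x$table$cdc_mm2_v2)))
  cat(sprintf("  mean %g%%-contour area %s (v1) / %s (v2) um^2\n",
              x$config$pct, fmt(x$table$area_um2_v1),
              fmt(x$table$area_um2_v2)))
  for (m in c("pcd_mm2", "cdc_mm2", "area_um2")) {
    st <- x$stats[[m]]
    if (is.null(st)) next
    cat(sprintf(
      "  %s: paired t = %.3g (p = %.3g), bias %.4g [%.4g, %.4g]\n",
      m, st$pairedT$t, st$pairedT$p, st$blandAltman$bias,
      st$blandAltman$biasCI[1], st$blandAltman$biasCI[2]))
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' Standard agreement plot: paired differences against pair means, with the
#' mean bias and the 95% limits of agreement.
#'
#' @param ba a `"blandAltman"` object.
#' @param xlab,ylab,main usual plot annotations.
#' @return the input, invisibly.
#' @export
plotBlandAltman <- function(ba, xlab = "Mean of visits",
                            ylab = "Visit 2 - visit 1", main = NULL) {
  stopifnot(inherits(ba, "blandAltman"))
  graphics::plot(ba$means, ba$differences, pch = 19, xlab = xlab,
                 ylab = ylab, main = main,
                 ylim = range(ba$differences, ba$loaLower, ba$loaUpper))
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = c(ba$loaLower, ba$loaUpper), lty = 2)
  invisible(ba)
}

#' Density matrix image
#'
#' Displays a [DensityMatrix] (or [DifferenceMap]) as an image in
#' micrometre coordinates, y pointing down as in the source ROI.
#'
#' @param dm a [DensityMatrix] or [DifferenceMap].
#' @param main plot title.
#' @return the input, invisibly.
#' @export
plotDensityMatrix <- function(dm, main = NULL) {
  v <- dm@values
  g <- dm@gridUm
  x <- (seq_len(ncol(v)) - 1L) * g
  y <- (seq_len(nrow(v)) - 1L) * g
  graphics::image(x, y, t(v)[, rev(seq_len(nrow(v)))],
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (um)", ylab = "y (um)", main = main,
                  useRaster = TRUE, asp = 1)
  invisible(dm)
}
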