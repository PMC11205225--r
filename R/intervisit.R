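#' Align two density matrices at their cone density centroids
#'
#' Computes the whole-cell translation that brings the CDC cell of the
#' second matrix onto the CDC cell of the first.  No rotation, scaling or
#' subpixel interpolation is applied: at typical grid spacings the
#' half-cell rounding this introduces is a fraction of a micrometre.
#'
#' @param dm1,dm2 [DensityMatrix] objects on the same grid spacing.
#' @param pct contour percentile used to define the CDCs.
#' @return list with `shift` (cells, (row, col), to apply to `dm2`
#'   indices), `cdc1`/`cdc2` (the two CDC cells), and the overlap ranges
#'   `rows1`, `cols1` (in `dm1` indices; the matching `dm2` indices are
#'   these minus `shift`).
#' @export
alignAtCdc <- function(dm1, dm2, pct = 80) {
  stopifnot(is(dm1, "DensityMatrix"), is(dm2, "DensityMatrix"))
  if (abs(dm1@gridUm - dm2@gridUm) > 1e-9 * dm1@gridUm)
    stop("matrices must share one grid spacing; rescale to a common scale first")
  c1 <- findCDC(dm1, pct)$cell
  c2 <- findCDC(dm2, pct)$cell
  shift <- c1 - c2                      # add to dm2 indices -> dm1 frame
  rows1 <- max(1L, 1L + shift[1L]):min(nrow(dm1@values),
                                       nrow(dm2@values) + shift[1L])
  cols1 <- max(1L, 1L + shift[2L]):min(ncol(dm1@values),
                                       ncol(dm2@values) + shift[2L])
  if (length(rows1) < 1L || length(cols1) < 1L ||
      rows1[1L] > rows1[length(rows1)] || cols1[1L] > cols1[length(cols1)])
    stop("aligned matrices have empty overlap")
  list(shift = as.integer(shift), cdc1 = c1, cdc2 = c2,
       rows1 = rows1, cols1 = cols1)
}

#' CDC-aligned difference map of two visits
#'
#' Subtracts the visit-1 matrix from the CDC-aligned visit-2 matrix over
#' their overlap and crops the result to a square of side `extentUm`
#' centred on the common CDC (default 300 um).  Cells invalid in either
#' input are `NA`.  If the overlap is smaller than the requested extent the
#' map is cropped to the overlap with a warning.
#'
#' @param dm1 visit-1 [DensityMatrix].
#' @param dm2 visit-2 [DensityMatrix].
#' @param extentUm side length of the output map in um.
#' @param pct contour percentile defining the CDCs.
#' @return a [DifferenceMap] (visit 2 minus visit 1).
#' @export
differenceMap <- function(dm1, dm2, extentUm = 300, pct = 80) {
  al <- alignAtCdc(dm1, dm2, pct)
  g <- dm1@gridUm
  half <- floor(extentUm / g / 2)
  rows <- max(al$rows1[1L], al$cdc1[1L] - half):
          min(al$rows1[length(al$rows1)], al$cdc1[1L] + half)
  cols <- max(al$cols1[1L], al$cdc1[2L] - half):
          min(al$cols1[length(al$cols1)], al$cdc1[2L] + half)
  if (length(rows) < 2L * half + 1L || length(cols) < 2L * half + 1L)
    warning(sprintf(
      "aligned overlap is smaller than the requested %g um extent; cropping to %g x %g um",
      extentUm, length(cols) * g, length(rows) * g))
  v1 <- dm1@values[rows, cols, drop = FALSE]
  v2 <- dm2@values[rows - al$shift[1L], cols - al$shift[2L], drop = FALSE]
  new("DifferenceMap", values = v2 - v1, gridUm = g,
      centerCell = as.integer(c(al$cdc1[1L] - rows[1L] + 1L,
                                al$cdc1[2L] - cols[1L] + 1L)),
      subjectId = dm1@subjectId)
}

setMethod("show", "DifferenceMap", function(object) {
  v <- object@values
  cat(sprintf(
    "DifferenceMap: %d x %d cells (%.3g um) | subject '%s'\n",
    nrow(v), ncol(v), object@gridUm, object@subjectId))
  if (any(!is.na(v)))
    cat(sprintf("  visit2 - visit1 range %.4g to %.4g cones/mm^2\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

#' Cross-section profile through the CDC of a difference map
#'
#' Extracts the single row (`"horizontal"`) or column (`"vertical"`) of the
#' difference map passing through the CDC cell and averages it in
#' contiguous bins of width `binUm` along the meridian.  Bins are centred
#' on the CDC: the bin spanning `[-binUm/2, +binUm/2)` contains the CDC.
#'
#' @param diff a [DifferenceMap].
#' @param meridian `"horizontal"` or `"vertical"`.
#' @param binUm bin width in um (default 5).
#' @return data.frame with `bin_center_um` (signed offset from the CDC),
#'   `mean`, `sd` and `n` (cells per bin); empty bins have `n = 0`.
#' @export
crossSection <- function(diff, meridian = c("horizontal", "vertical"),
                         binUm = 5) {
  stopifnot(is(diff, "DifferenceMap"))
  meridian <- match.arg(meridian)
  cc <- diff@centerCell
  if (meridian == "horizontal") {
    vals <- diff@values[cc[1L], ]
    off <- (seq_along(vals) - cc[2L]) * diff@gridUm
  } else {
    vals <- diff@values[, cc[2L]]
    off <- (seq_along(vals) - cc[1L]) * diff@gridUm
  }
  bin <- round(off / binUm)
  bins <- seq(min(bin), max(bin))
  res <- lapply(bins, function(b) {
    v <- vals[bin == b]
    v <- v[!is.na(v)]
    data.frame(bin_center_um = b * binUm,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               n = length(v))
  })
  do.call(rbind, res)
}

#' Composite cross-section profile across subjects
#'
#' Averages per-subject cross-section profiles on their shared bin grid:
#' for every bin centre, the mean and SD across the subjects contributing a
#' non-empty bin there, with the contributing count recorded.
#'
#' @param profiles list of per-subject profiles from [crossSection()]
#'   (>= 2), all produced with the same bin width.
#' @return data.frame with `bin_center_um`, `mean`, `sd` (across subjects)
#'   and `n` (subjects per bin).
#' @export
compositeProfile <- function(profiles) {
  if (length(profiles) < 2L)
    stop("composite profile needs at least 2 per-subject profiles")
  centers <- sort(unique(unlist(lapply(profiles, `[[`, "bin_center_um"))))
  steps <- unique(unlist(lapply(profiles, function(p)
    diff(sort(p$bin_center_um)))))
  if (length(unique(round(steps, 9))) > 1L)
    stop("profiles are not on a common bin grid")
  res <- lapply(centers, function(ct) {
    v <- vapply(profiles, function(p) {
      i <- which(abs(p$bin_center_um - ct) < 1e-9)
      if (length(i) == 1L && p$n[i] > 0L) p$mean[i] else NA_real_
    }, numeric(1))
    v <- v[!is.na(v)]
    data.frame(bin_center_um = ct,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               n = length(v))
  })
  do.call(rbind, res)
}
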