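#' Read a cone coordinate file with its metadata
#'
#' Reads a two-column (x, y) coordinate table in pixel units plus the scale
#' metadata needed to interpret it.  Metadata may come from a JSON sidecar
#' (`{"um_per_pixel": ..., "roi_side_um": ..., "subject_id": ...,
#' "visit": ..., "axial_length_mm": ...}`), from a row of a manifest
#' data.frame, or from the explicit arguments, in increasing order of
#' precedence.
#'
#' A header line is auto-detected (a first line that does not parse as two
#' numbers is treated as a header).  Malformed rows raise a parse error
#' naming the offending line; duplicate points raise a validation error.
#'
#' @param coordPath path to the coordinate CSV/TSV file.
#' @param metadataPath path to a JSON metadata sidecar; defaults to
#'   `coordPath` with its extension replaced by `.json` when that file
#'   exists.
#' @param metadata named list or one-row data.frame of metadata fields
#'   (alternative to a sidecar, e.g. a manifest table row).
#' @param umPerPixel,roiSideUm,subjectId,visit,axialLengthMm explicit
#'   overrides for individual metadata fields.
#' @param sep field separator; `""` auto-detects comma/whitespace.
#' @return a [ConeField].
#' @seealso [writeConeField()] for the inverse operation.
#' @export
readConeField <- function(coordPath, metadataPath = NULL, metadata = NULL,
                          umPerPixel = NULL, roiSideUm = NULL,
                          subjectId = NULL, visit = NULL,
                          axialLengthMm = NULL, sep = "") {
  if (!file.exists(coordPath)) stop("coordinate file not found: ", coordPath)
  lines <- readLines(coordPath, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("coordinate file is empty: ", coordPath)
  if (sep == "") sep <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else ""

  splitrow <- function(ln) {
    parts <- if (sep == ",") strsplit(ln, ",", fixed = TRUE)[[1L]]
             else strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    trimws(parts)
  }
  first <- suppressWarnings(as.numeric(splitrow(lines[[1L]])))
  hasHeader <- any(is.na(first)) || length(first) != 2L
  body <- if (hasHeader) lines[-1L] else lines
  offset <- if (hasHeader) 1L else 0L
  if (length(body) == 0L) stop("no coordinate rows in ", coordPath)

  co <- matrix(NA_real_, nrow = length(body), ncol = 2L)
  for (i in seq_along(body)) {
    parts <- splitrow(body[[i]])
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2L || any(is.na(vals)))
      stop(sprintf("cannot parse line %d of '%s': \"%s\"",
                   i + offset, coordPath, body[[i]]))
    co[i, ] <- vals
  }

  meta <- list()
  if (is.null(metadataPath)) {
    cand <- sub("\\.[^.]*$", ".json", coordPath)
    if (cand != coordPath && file.exists(cand)) metadataPath <- cand
  }
  if (!is.null(metadataPath)) {
    if (!file.exists(metadataPath))
      stop("metadata file not found: ", metadataPath)
    meta <- jsonlite::read_json(metadataPath, simplifyVector = TRUE)
  }
  if (!is.null(metadata)) meta[names(metadata)] <- as.list(metadata)

  pick <- function(override, key, default = NULL) {
    if (!is.null(override)) return(override)
    if (!is.null(meta[[key]])) return(meta[[key]])
    default
  }
  ump <- pick(umPerPixel, "um_per_pixel")
  side <- pick(roiSideUm, "roi_side_um")
  if (is.null(ump) || is.null(side))
    stop("missing scale metadata: 'um_per_pixel' and 'roi_side_um' are ",
         "required (sidecar JSON, manifest row, or explicit arguments)")
  ConeField(co, ump, side,
            subjectId = pick(subjectId, "subject_id", ""),
            visit = pick(visit, "visit", 1L),
            axialLengthMm = pick(axialLengthMm, "axial_length_mm", NA_real_))
}

#' Write a ConeField to a coordinate file plus JSON sidecar
#'
#' Writes the pixel coordinates as a two-column CSV (no header) at full
#' double precision, and the scale metadata as a JSON sidecar, so that
#' [readConeField()] round-trips losslessly.
#'
#' @param field a [ConeField].
#' @param coordPath output CSV path.
#' @param metadataPath output JSON path; default replaces the coordinate
#'   file's extension with `.json`.
#' @return `coordPath`, invisibly.
#' @export
writeConeField <- function(field, coordPath, metadataPath = NULL) {
  stopifnot(is(field, "ConeField"))
  if (is.null(metadataPath))
    metadataPath <- sub("\\.[^.]*$", ".json", coordPath)
  co <- field@coords
  writeLines(sprintf("%.17g,%.17g", co[, 1], co[, 2]), coordPath)
  meta <- list(um_per_pixel = field@umPerPixel,
               roi_side_um = field@roiSideUm,
               subject_id = field@subjectId,
               visit = field@visit,
               axial_length_mm = field@axialLengthMm)
  jsonlite::write_json(meta, metadataPath, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(coordPath)
}

#' Micrometres per degree of visual angle from axial length
#'
#' Converts an eye's axial length to the retinal magnification factor using
#' Bennett's adjusted axial length model: `q = 0.01306 * (AL - 1.82)` mm of
#' retina per degree of visual angle, returned in micrometres per degree.
#' This is the package's documented convention for linear-to-angular
#' density conversion; it is isolated here so an alternative model can be
#' substituted in one place.
#'
#' @param axialLengthMm axial length in millimetres.  Values outside the
#'   physiological sanity range 20-30 mm trigger a warning, not an error.
#' @return micrometres per degree.
#' @examples
#' umPerDegree(24)     # 289.7 um/deg
#' umPerDegree(23.91)  # 288.5 um/deg
#' @export
umPerDegree <- function(axialLengthMm) {
  if (!is.numeric(axialLengthMm) || any(!is.finite(axialLengthMm)))
    stop("'axialLengthMm' must be finite and numeric")
  if (any(axialLengthMm < 20 | axialLengthMm > 30))
    warning("axial length outside the 20-30 mm sanity range")
  1000 * 0.01306 * (axialLengthMm - 1.82)
}
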