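#' Axial-length-corrected lateral scale
#'
#' The physical length of a B-scan is the nominal scan length multiplied by
#' the ratio of the participant's axial length to the scanner's assumed
#' axial length (24 mm); dividing by the number of A-scans per B-scan gives
#' the lateral sampling pitch.
#'
#' @param nominal_length_mm nominal scan length (mm).
#' @param axial_length_mm participant's measured axial length (mm).
#' @param n_ascans A-scans per B-scan (default 1000).
#' @param assumed_al_mm scanner's assumed axial length (mm, default 24).
#' @return micrometres per A-scan.
#' @export
#' @examples
#' lateral_scale_um_per_ascan(6, 24)        # 6 um per A-scan
#' lateral_scale_um_per_ascan(7, 27.06)     # 7.8925 um per A-scan
lateral_scale_um_per_ascan <- function(nominal_length_mm, axial_length_mm,
                                       n_ascans = 1000, assumed_al_mm = 24) {
  if (any(c(nominal_length_mm, axial_length_mm, n_ascans, assumed_al_mm) <= 0)) {
    abort("All scale arguments must be strictly positive.")
  }
  nominal_length_mm * (axial_length_mm / assumed_al_mm) / n_ascans * 1000
}

#' Layer thickness profiles from boundary contours
#'
#' Converts six boundary traces (pixel y per A-scan column) into physically
#' scaled thickness profiles for the four analysed layers: TRT (ILM to RPE),
#' GCL (RNFL/GCL to GCL/IPL), IPL (GCL/IPL to IPL/INL), and GCIPL (RNFL/GCL
#' to IPL/INL). Thickness is (lower - upper boundary) x axial um/px; the
#' abscissa is column x lateral um-per-A-scan (scan coordinates, recentered
#' later by [eccentricity_axis()]). No smoothing is applied.
#'
#' @param contours a `bscan_contours` object, or a data frame with columns
#'   `column_px` and the six boundaries `ILM`, `RNFL_GCL`, `GCL_IPL`,
#'   `IPL_INL`, `OPL`, `RPE` (y in px, row 0 = top).
#' @param axial_um_per_px axial image scale (um per pixel); taken from
#'   `contours$meta` when available.
#' @param um_per_ascan lateral scale (um per A-scan); computed from metadata
#'   when available, see [lateral_scale_um_per_ascan()].
#' @param meta optional scan metadata list (`eye`, `orientation`, ...).
#' @return a tibble with columns `x_mm`, `TRT`, `GCL`, `IPL`, `GCIPL`
#'   (thickness in um) and attribute `meta`.
#' @export
thickness_profiles <- function(contours, axial_um_per_px = NULL,
                               um_per_ascan = NULL, meta = NULL) {
  if (inherits(contours, "bscan_contours")) {
    meta <- meta %||% contours$meta
    contours <- contours$contours
  }
  axial_um_per_px <- axial_um_per_px %||% meta$axial_um_per_px %||% 3.24
  um_per_ascan <- um_per_ascan %||% meta$um_per_ascan %||%
    lateral_scale_um_per_ascan(meta$nominal_length_mm %||% 6,
                               meta$axial_length_mm %||% 24,
                               n_ascans = meta$n_ascans %||% nrow(contours))
  miss <- setdiff(boundary_names, names(contours))
  if (length(miss)) {
    abort(paste0("Contours are missing boundaries: ", paste(miss, collapse = ", ")))
  }
  cb <- as.matrix(contours[, boundary_names])
  # columnwise ordering audit, reporting the first offending column and pair
  for (j in seq_len(ncol(cb) - 1L)) {
    bad <- which(cb[, j + 1L] - cb[, j] < -1e-9)
    if (length(bad)) {
      abort(sprintf("Boundary order violated at column %d: %s lies below %s.",
                    bad[1] - 1L, boundary_names[j], boundary_names[j + 1L]))
    }
  }
  x_mm <- (contours$column_px) * um_per_ascan / 1000
  out <- tibble(
    x_mm = x_mm,
    TRT = (cb[, "RPE"] - cb[, "ILM"]) * axial_um_per_px,
    GCL = (cb[, "GCL_IPL"] - cb[, "RNFL_GCL"]) * axial_um_per_px,
    IPL = (cb[, "IPL_INL"] - cb[, "GCL_IPL"]) * axial_um_per_px,
    GCIPL = (cb[, "IPL_INL"] - cb[, "RNFL_GCL"]) * axial_um_per_px
  )
  attr(out, "meta") <- meta
  out
}

#' Read / write contour CSV files
#'
#' Plain-CSV exchange format for segmentation contours: columns `column_px`
#' plus the six boundary y-values in px (row 0 = top), as exported from
#' assisted segmentation. Metadata travels in a JSON sidecar.
#'
#' @param path CSV path.
#' @param meta_path optional JSON sidecar with scan metadata.
#' @return `read_contours_csv()`: a `bscan_contours` object (without truth).
#' @export
read_contours_csv <- function(path, meta_path = NULL) {
  df <- as_tibble(utils::read.csv(path, check.names = FALSE))
  meta <- if (!is.null(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(contours = df, truth = NULL, meta = meta),
            class = "bscan_contours")
}

#' @rdname read_contours_csv
#' @param contours a `bscan_contours` object.
#' @export
write_contours_csv <- function(contours, path, meta_path = NULL) {
  stopifnot(inherits(contours, "bscan_contours"))
  utils::write.csv(contours$contours, path, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(contours$meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
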