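#' Interpolate a thickness profile onto the analysis grid
#'
#' Linear interpolation of each layer at fixed 100-um eccentricity
#' increments spanning +/- 2.5 mm: 51 samples per scan, endpoints included.
#' Profiles that do not cover the full extent raise an error naming the
#' missing range (such scans are excluded, not extrapolated).
#'
#' @param profile tibble from [eccentricity_axis()] (`ecc_mm` + layer cols).
#' @param step_mm grid step (default 0.1 mm).
#' @param halfwidth_mm grid half-width (default 2.5 mm).
#' @return tibble `ecc_mm`, `quadrant`, layer columns; 51 rows at defaults.
#'   Attribute `meta` is carried over.
#' @export
interpolate_grid <- function(profile, step_mm = 0.1, halfwidth_mm = 2.5) {
  if (!"ecc_mm" %in% names(profile)) {
    abort("`profile` must have an `ecc_mm` column (run eccentricity_axis()).")
  }
  lo <- min(profile$ecc_mm); hi <- max(profile$ecc_mm)
  if (lo > -halfwidth_mm + 1e-9 || hi < halfwidth_mm - 1e-9) {
    abort(sprintf(
      "SHORT_COVERAGE: profile spans [%.3f, %.3f] mm; missing %s.",
      lo, hi,
      paste(c(
        if (lo > -halfwidth_mm) sprintf("[%.3f, %.3f]", -halfwidth_mm, lo),
        if (hi < halfwidth_mm) sprintf("[%.3f, %.3f]", hi, halfwidth_mm)
      ), collapse = " and ")))
  }
  grid <- seq(-halfwidth_mm, halfwidth_mm, by = step_mm)
  layer_cols <- setdiff(names(profile), c("ecc_mm", "quadrant"))
  out <- tibble(ecc_mm = grid)
  for (ly in layer_cols) {
    out[[ly]] <- approx(profile$ecc_mm, profile[[ly]], xout = grid,
                        ties = "ordered")$y
  }
  meta <- attr(profile, "meta") %||% list()
  orientation <- meta$orientation %||% "horizontal"
  pos_lab <- if (orientation == "horizontal") "nasal" else "superior"
  neg_lab <- if (orientation == "horizontal") "temporal" else "inferior"
  out$quadrant <- ifelse(out$ecc_mm > 0, pos_lab,
                         ifelse(out$ecc_mm < 0, neg_lab, "fovea"))
  out <- relocate(out, "ecc_mm", "quadrant")
  attr(out, "meta") <- meta
  attr(out, "gridded") <- TRUE
  out
}

quadrant_sign <- function(quadrant) {
  switch(quadrant,
    nasal = , superior = 1,
    temporal = , inferior = -1,
    abort(sprintf("Unknown quadrant '%s'.", quadrant)))
}

#' Quadrant area under the thickness curve
#'
#' Trapezoidal integration of one layer's gridded thickness over one
#' quadrant (eccentricity 0 to +/- 2.5 mm; the foveal sample at 0 is shared
#' by both quadrants). Thickness is converted um -> mm, so the area is in
#' mm^2.
#'
#' @param grid gridded profile from [interpolate_grid()].
#' @param layer layer column name (e.g. `"GCL"`).
#' @param quadrant `"nasal"`, `"temporal"`, `"superior"`, `"inferior"`.
#' @return AUC in mm^2.
#' @export
#' @examples
#' # constant 100 um over a 2.5 mm quadrant -> 0.25 mm^2
quadrant_auc <- function(grid, layer, quadrant) {
  if (!isTRUE(attr(grid, "gridded"))) {
    abort("`grid` must come from interpolate_grid().")
  }
  if (!layer %in% names(grid)) abort(sprintf("No layer column '%s'.", layer))
  sgn <- quadrant_sign(quadrant)
  side <- grid[sgn * grid$ecc_mm >= 0, ]
  x <- sgn * side$ecc_mm
  o <- order(x)
  trapz(x[o], side[[layer]][o] / 1000)
}

#' Sum of the four quadrant AUCs
#'
#' @param auc named or unnamed numeric vector of the four quadrant AUCs
#'   (temporal, nasal, inferior, superior). A missing quadrant (NA) makes
#'   the sum NA: participants lacking one orientation are reported missing,
#'   never imputed.
#' @return mm^2.
#' @export
summed_auc <- function(auc) {
  if (length(auc) != 4L) abort("`auc` must contain exactly four quadrant AUCs.")
  if (any(is.na(auc))) return(NA_real_)
  sum(auc)
}

#' Quadrant asymmetry ratio
#'
#' Nasal:temporal (horizontal scans) or superior:inferior (vertical scans)
#' AUC ratio.
#'
#' @param auc_positive AUC of the nasal or superior quadrant (mm^2).
#' @param auc_negative AUC of the temporal or inferior quadrant (mm^2).
#' @return dimensionless ratio.
#' @export
asymmetry_ratio <- function(auc_positive, auc_negative) {
  if (any(auc_negative <= 0)) abort("Denominator quadrant AUC must be > 0.")
  auc_positive / auc_negative
}

#' Percent contribution of the GCL to the GCIPL
#'
#' @param gcl,gcipl gridded thickness vectors (um) on the same grid, or a
#'   gridded profile tibble with `GCL` and `GCIPL` columns.
#' @param mask_below_um GCIPL values below this (um) give NA (default 1).
#' @return percent vector (or tibble with `gcl_fraction_pct` added).
#' @export
gcl_fraction <- function(gcl, gcipl = NULL, mask_below_um = 1) {
  if (is.data.frame(gcl)) {
    grid <- gcl
    if (!all(c("GCL", "GCIPL") %in% names(grid))) {
      abort("Gridded profile needs `GCL` and `GCIPL` columns.")
    }
    grid$gcl_fraction_pct <- gcl_fraction(grid$GCL, grid$GCIPL, mask_below_um)
    return(grid)
  }
  if (length(gcl) != length(gcipl)) abort("GCL and GCIPL grids differ in length.")
  out <- 100 * gcl / gcipl
  out[gcipl < mask_below_um] <- NA_real_
  out
}

#' Average two repeat measurements
#'
#' Pointwise mean of two gridded profiles of the same scan (same grid, eye,
#' and orientation), used ahead of AUC so each scan contributes one profile.
#'
#' @param profile_1,profile_2 gridded profiles from [interpolate_grid()].
#' @return gridded profile of pointwise means.
#' @export
average_repeats <- function(profile_1, profile_2) {
  if (!identical(dim(profile_1), dim(profile_2)) ||
      !isTRUE(all.equal(profile_1$ecc_mm, profile_2$ecc_mm))) {
    abort("Repeat profiles are on different grids.")
  }
  m1 <- attr(profile_1, "meta") %||% list()
  m2 <- attr(profile_2, "meta") %||% list()
  for (f in c("eye", "orientation")) {
    if (!is.null(m1[[f]]) && !is.null(m2[[f]]) && !identical(m1[[f]], m2[[f]])) {
      abort(sprintf("Repeat metadata mismatch on '%s' (%s vs %s).",
                    f, m1[[f]], m2[[f]]))
    }
  }
  out <- profile_1
  for (ly in setdiff(names(out), c("ecc_mm", "quadrant"))) {
    out[[ly]] <- (profile_1[[ly]] + profile_2[[ly]]) / 2
  }
  out
}

#' Per-layer quadrant metrics for one participant-eye
#'
#' Combines a horizontal and (optionally) a vertical gridded profile into
#' the per-quadrant AUC table: temporal/nasal from the horizontal scan,
#' inferior/superior from the vertical, the four-quadrant sum (NA when an
#' orientation is missing), and the two asymmetry ratios.
#'
#' @param grid_h gridded horizontal profile (or `NULL`).
#' @param grid_v gridded vertical profile (or `NULL`).
#' @param layers layer columns to evaluate.
#' @return tibble: `layer`, `auc_T`, `auc_N`, `auc_I`, `auc_S`, `auc_sum`,
#'   `ratio_NT`, `ratio_SI`.
#' @export
quadrant_metrics <- function(grid_h, grid_v = NULL,
                             layers = c("TRT", "GCL", "IPL", "GCIPL")) {
  if (is.null(grid_h) && is.null(grid_v)) abort("At least one orientation is required.")
  rows <- lapply(layers, function(ly) {
    auc_t <- if (!is.null(grid_h)) quadrant_auc(grid_h, ly, "temporal") else NA_real_
    auc_n <- if (!is.null(grid_h)) quadrant_auc(grid_h, ly, "nasal") else NA_real_
    auc_i <- if (!is.null(grid_v)) quadrant_auc(grid_v, ly, "inferior") else NA_real_
    auc_s <- if (!is.null(grid_v)) quadrant_auc(grid_v, ly, "superior") else NA_real_
    tibble(layer = ly, auc_T = auc_t, auc_N = auc_n, auc_I = auc_i,
           auc_S = auc_s,
           auc_sum = summed_auc(c(auc_t, auc_n, auc_i, auc_s)),
           ratio_NT = if (!is.null(grid_h)) asymmetry_ratio(auc_n, auc_t) else NA_real_,
           ratio_SI = if (!is.null(grid_v)) asymmetry_ratio(auc_s, auc_i) else NA_real_)
  })
  bind_rows(rows)
}
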