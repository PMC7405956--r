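#' Synthetic foveal phenotype
#'
#' Defines the generative model of a foveal cross-section. Each retinal layer
#' follows a baseline-plus-difference-of-Gaussians thickness profile
#' \deqn{T(x) = \max(0,\; B - a_p e^{-x^2/2\sigma_p^2} + a_r e^{-x^2/2\sigma_r^2})}
#' with baseline \eqn{B} (um), pit amplitude \eqn{a_p} (um) and width
#' \eqn{\sigma_p} (mm), and rim amplitude \eqn{a_r} (um) and width
#' \eqn{\sigma_r} (mm). A multiplicative side factor `rho_nt` (nasal) or
#' `rho_si` (superior) scales the whole profile on the positive half-axis,
#' blended smoothly across the center by a logistic weight whose transition
#' (12\%--88\%) spans +/- 0.2 mm, so nasal:temporal quadrant AUC ratios track
#' `rho_nt` closely. `rho_nt = rho_si = 1` gives a radially symmetric phantom.
#'
#' Presets span the control-to-hypoplasia spectrum: `"control"` has a fully
#' excavated pit; `"grade1"` to `"grade4"` progressively shrink pit amplitude
#' (`pit_scale` 0.7, 0.45, 0.2, 0), with `"grade4"` showing essentially no
#' foveal depression.
#'
#' @param preset one of `"control"`, `"grade1"`, `"grade2"`, `"grade3"`,
#'   `"grade4"`.
#' @param rho_nt nasal side multiplier (>= 0), applied on horizontal scans.
#' @param rho_si superior side multiplier (>= 0), applied on vertical scans.
#' @param pit_scale optional override of the preset pit-amplitude scale.
#' @param layers optional tibble overriding the per-layer parameters; columns
#'   `layer`, `baseline_um`, `pit_amp_um`, `pit_sigma_mm`, `rim_amp_um`,
#'   `rim_sigma_mm` for layers RNFL, GCL, IPL, INL_OPL, OUTER.
#' @return an object of class `fovea_phenotype`.
#' @export
#' @examples
#' ph <- fovea_phenotype("control")
#' ph$layers
fovea_phenotype <- function(preset = c("control", "grade1", "grade2", "grade3", "grade4"),
                            rho_nt = 1, rho_si = 1, pit_scale = NULL,
                            layers = NULL) {
  preset <- match.arg(preset)
  if (!is.numeric(rho_nt) || length(rho_nt) != 1L || rho_nt < 0) {
    abort("`rho_nt` must be a single number >= 0.")
  }
  if (!is.numeric(rho_si) || length(rho_si) != 1L || rho_si < 0) {
    abort("`rho_si` must be a single number >= 0.")
  }
  scale <- pit_scale %||% switch(preset,
    control = 1, grade1 = 0.7, grade2 = 0.45, grade3 = 0.2, grade4 = 0
  )
  base <- layers %||% phantom_layer_defaults()
  base <- as_tibble(base)
  req <- c("layer", "baseline_um", "pit_amp_um", "pit_sigma_mm",
           "rim_amp_um", "rim_sigma_mm")
  if (!all(req %in% names(base))) {
    abort(paste0("`layers` must have columns: ", paste(req, collapse = ", ")))
  }
  base$pit_amp_um <- base$pit_amp_um * scale
  if (any(base$pit_sigma_mm <= 0) || any(base$rim_sigma_mm <= 0)) {
    abort("Gaussian widths must be strictly positive.")
  }
  if (any(base$pit_sigma_mm >= base$rim_sigma_mm)) {
    abort("Pit width sigma_p must be smaller than rim width sigma_r for every layer.")
  }
  ph <- structure(
    list(preset = preset, rho_nt = rho_nt, rho_si = rho_si,
         pit_scale = scale, layers = base),
    class = "fovea_phenotype"
  )
  # positivity audit on +/- 2.5 mm at the largest side multiplier; a clamped
  # profile stays usable but the closed-form AUC oracle no longer applies
  xs <- seq(-2.5, 2.5, by = 0.005)
  clamped <- FALSE
  for (ly in base$layer) {
    tt <- phenotype_thickness(ph, xs, ly, axis = "nt", clamp = FALSE)
    if (any(tt <= 0)) clamped <- TRUE
    tt <- phenotype_thickness(ph, xs, ly, axis = "si", clamp = FALSE)
    if (any(tt <= 0)) clamped <- TRUE
  }
  attr(ph, "clamped") <- clamped
  if (clamped) {
    warn("Phenotype yields non-positive layer thickness somewhere on +/-2.5 mm; profiles will be clamped at 0 and the closed-form AUC oracle does not apply.")
  }
  ph
}

# default per-layer DoG parameters (um / mm), control morphology
phantom_layer_defaults <- function() {
  tibble(
    layer        = phantom_layers,
    baseline_um  = c(12, 30, 37, 55, 125),
    pit_amp_um   = c(9, 38, 31, 36, -30),
    pit_sigma_mm = c(0.40, 0.30, 0.33, 0.35, 0.35),
    rim_amp_um   = c(4, 16, 8, 6, 0),
    rim_sigma_mm = c(1.30, 1.00, 1.00, 0.90, 1.00)
  )
}

#' @export
print.fovea_phenotype <- function(x, ...) {
  cat(sprintf("<fovea_phenotype> preset=%s pit_scale=%.2f rho_nt=%.3f rho_si=%.3f\n",
              x$preset, x$pit_scale, x$rho_nt, x$rho_si))
  print(x$layers)
  invisible(x)
}

# half-width (mm) over which the side factor blends across x = 0; the
# logistic weight moves 0.12 -> 0.88 within +/- this distance
blend_halfwidth_mm <- 0.2
blend_scale_mm <- blend_halfwidth_mm / 2

# unblended one-sided DoG thickness (um) at |x|, before the rho factor
dog_thickness <- function(x, p) {
  p$baseline_um -
    p$pit_amp_um * exp(-x^2 / (2 * p$pit_sigma_mm^2)) +
    p$rim_amp_um * exp(-x^2 / (2 * p$rim_sigma_mm^2))
}

# generative thickness of one layer along one axis (nt: nasal positive;
# si: superior positive), blended across x = 0
phenotype_thickness <- function(phenotype, x_mm, layer, axis = c("nt", "si"),
                                clamp = TRUE) {
  axis <- match.arg(axis)
  rho <- if (axis == "nt") phenotype$rho_nt else phenotype$rho_si
  p <- phenotype$layers[phenotype$layers$layer == layer, ]
  if (nrow(p) != 1L) abort(sprintf("Unknown layer '%s'.", layer))
  base <- dog_thickness(x_mm, p)
  w <- stats::plogis(x_mm / blend_scale_mm)
  tt <- (1 - w) * base + w * rho * base
  if (clamp) pmax(tt, 0) else tt
}

#' Ground-truth boundary contours for a synthetic fovea
#'
#' Evaluates the phenotype's layer thickness model on an A-scan grid and
#' stacks layers upward from a flat RPE to produce the six boundary traces
#' (ILM, RNFL/GCL, GCL/IPL, IPL/INL, OPL, RPE) in image pixel coordinates
#' (row 0 = top), together with the noise-free ground-truth thickness
#' profiles in anatomic coordinates (positive = nasal or superior).
#'
#' Image columns follow scan geometry: on OD horizontal scans image-left is
#' temporal, so anatomic +x increases with column; OS horizontal scans are
#' mirrored. Vertical scans map image-left to inferior for both eyes.
#'
#' @param phenotype a [fovea_phenotype()].
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param eye `"OD"` or `"OS"`.
#' @param n_ascans number of A-scan columns.
#' @param nominal_length_mm nominal scan length (mm).
#' @param axial_length_mm the eye's axial length (mm); rescales the lateral
#'   grid via [lateral_scale_um_per_ascan()].
#' @param axial_um_per_px axial scale of the rendered image (um per pixel).
#' @param rpe_depth_um image depth of the flat RPE (um from the top row).
#' @param seg_noise_sd_px SD (px) of independent Gaussian jitter added to
#'   each boundary trace, emulating segmentation variability; ordering is
#'   re-enforced after jitter. 0 = noise-free ground truth.
#' @param seed RNG seed, required when `seg_noise_sd_px > 0`.
#' @return an object of class `bscan_contours`: a list with `contours`
#'   (tibble `column_px`, `ILM`, ..., `RPE` in px), `truth` (long tibble
#'   `x_mm`, `layer`, `thickness_um` including TRT and GCIPL), and `meta`.
#' @export
make_boundary_profiles <- function(phenotype,
                                   orientation = c("horizontal", "vertical"),
                                   eye = c("OD", "OS"),
                                   n_ascans = 600,
                                   nominal_length_mm = 6,
                                   axial_length_mm = 24,
                                   axial_um_per_px = 3.24,
                                   rpe_depth_um = 480,
                                   seg_noise_sd_px = 0,
                                   seed = NULL) {
  stopifnot(inherits(phenotype, "fovea_phenotype"))
  orientation <- match.arg(orientation)
  eye <- match.arg(eye)
  um_per_ascan <- lateral_scale_um_per_ascan(nominal_length_mm, axial_length_mm,
                                             n_ascans = n_ascans)
  # anatomic abscissa, centered on the (true) fovea at scan middle
  x_mm <- (seq_len(n_ascans) - 1 - (n_ascans - 1) / 2) * um_per_ascan / 1000
  if (max(x_mm) < 2.5 || min(x_mm) > -2.5) {
    abort(sprintf(
      "Scan grid covers [%.2f, %.2f] mm but must reach +/-2.5 mm around the fovea.",
      min(x_mm), max(x_mm)))
  }
  axis <- if (orientation == "horizontal") "nt" else "si"
  thick <- sapply(phantom_layers, function(ly) {
    phenotype_thickness(phenotype, x_mm, ly, axis = axis)
  })
  # stack upward from the flat RPE (um depth -> px, row 0 at top)
  depth <- cbind(
    RPE = rep(rpe_depth_um, n_ascans),
    OPL = rpe_depth_um - thick[, "OUTER"],
    IPL_INL = rpe_depth_um - thick[, "OUTER"] - thick[, "INL_OPL"],
    GCL_IPL = rpe_depth_um - thick[, "OUTER"] - thick[, "INL_OPL"] - thick[, "IPL"],
    RNFL_GCL = rpe_depth_um - rowSums(thick[, c("OUTER", "INL_OPL", "IPL", "GCL")]),
    ILM = rpe_depth_um - rowSums(thick)
  )
  ypx <- depth[, rev(colnames(depth))] / axial_um_per_px
  if (any(ypx < 0)) abort("Layers exceed image depth; increase `rpe_depth_um`.")
  if (seg_noise_sd_px > 0) {
    if (is.null(seed)) abort("`seed` is required when `seg_noise_sd_px` > 0.")
    ypx <- with_seed(seed, {
      ypx + matrix(rnorm(length(ypx), sd = seg_noise_sd_px), nrow(ypx))
    })
    # re-enforce top-to-bottom ordering after jitter
    for (j in 2:ncol(ypx)) ypx[, j] <- pmax(ypx[, j], ypx[, j - 1])
  }
  flip <- (orientation == "horizontal" && eye == "OS")
  if (flip) ypx <- ypx[rev(seq_len(n_ascans)), , drop = FALSE]
  contours <- as_tibble(as.data.frame(ypx))
  contours <- bind_cols(tibble(column_px = seq_len(n_ascans) - 1L), contours)
  truth <- as_tibble(as.data.frame(thick))
  truth$TRT <- rowSums(thick)
  truth$GCIPL <- thick[, "GCL"] + thick[, "IPL"]
  truth$x_mm <- x_mm
  truth <- pivot_longer(truth, -"x_mm", names_to = "layer",
                        values_to = "thickness_um")
  meta <- list(
    eye = eye, orientation = orientation,
    nominal_length_mm = nominal_length_mm, n_ascans = n_ascans,
    axial_length_mm = axial_length_mm, axial_um_per_px = axial_um_per_px,
    um_per_ascan = um_per_ascan, rpe_depth_um = rpe_depth_um,
    center_col = (n_ascans - 1) / 2, mirrored = flip,
    seg_noise_sd_px = seg_noise_sd_px
  )
  structure(list(contours = contours, truth = truth, meta = meta),
            class = "bscan_contours")
}

#' Closed-form quadrant AUC of a synthetic phenotype
#'
#' Exact area under one layer's generative thickness curve over one quadrant
#' (0 to `halfwidth_mm` of eccentricity), in mm^2. The one-sided profile
#' \eqn{\rho (B - a_p g_p + a_r g_r)} integrates in closed form via the
#' Gaussian error function. When the generative profile would be clamped at
#' zero on the quadrant the closed form no longer applies and the value is
#' computed by adaptive quadrature of the clamped profile instead, flagged
#' via the `"clamped"` attribute.
#'
#' @param phenotype a [fovea_phenotype()].
#' @param layer one of RNFL, GCL, IPL, INL_OPL, OUTER, GCIPL, TRT.
#' @param quadrant `"nasal"`, `"temporal"`, `"superior"`, or `"inferior"`.
#' @param halfwidth_mm quadrant extent (mm).
#' @return AUC in mm^2, with attribute `clamped` (logical).
#' @export
#' @examples
#' ph <- fovea_phenotype("control")
#' analytic_quadrant_auc(ph, "GCL", "nasal")
analytic_quadrant_auc <- function(phenotype, layer,
                                  quadrant = c("nasal", "temporal", "superior", "inferior"),
                                  halfwidth_mm = 2.5) {
  stopifnot(inherits(phenotype, "fovea_phenotype"))
  quadrant <- match.arg(quadrant)
  rho <- switch(quadrant,
    nasal = phenotype$rho_nt, superior = phenotype$rho_si,
    temporal = 1, inferior = 1
  )
  lys <- switch(layer, GCIPL = c("GCL", "IPL"), TRT = phantom_layers, layer)
  if (!all(lys %in% phenotype$layers$layer)) {
    abort(sprintf("Unknown layer '%s'.", layer))
  }
  xs <- seq(0, halfwidth_mm, by = 0.002)
  total <- 0
  clamped <- FALSE
  for (ly in lys) {
    p <- phenotype$layers[phenotype$layers$layer == ly, ]
    side <- rho * dog_thickness(xs, p)
    if (any(side <= 0)) {
      clamped <- TRUE
      total <- total + integrate(function(x) pmax(rho * dog_thickness(x, p), 0),
                                 0, halfwidth_mm, rel.tol = 1e-10,
                                 subdivisions = 500L)$value / 1000
    } else {
      h <- halfwidth_mm
      total <- total + rho * (
        p$baseline_um * h -
          p$pit_amp_um * p$pit_sigma_mm * sqrt(pi / 2) * erf(h / (p$pit_sigma_mm * sqrt(2))) +
          p$rim_amp_um * p$rim_sigma_mm * sqrt(pi / 2) * erf(h / (p$rim_sigma_mm * sqrt(2)))
      ) / 1000
    }
  }
  structure(total, clamped = clamped)
}

#' Inter- and intra-frame motion model for rendered stacks
#'
#' @param lateral_sd_px SD of per-frame integer lateral shifts (px).
#' @param axial_sd_px SD of per-frame integer axial shifts (px).
#' @param strip_jitter_sd_px SD of additional per-strip integer axial jitter
#'   within a frame (px), emulating intra-frame motion at nystagmus scale.
#' @param strip_width_px column width of the jittered strips.
#' @param drop_prob probability that a frame is replaced by structureless
#'   noise (tracking loss).
#' @return an object of class `motion_model`.
#' @export
motion_model <- function(lateral_sd_px = 3, axial_sd_px = 2,
                         strip_jitter_sd_px = 1, strip_width_px = 64,
                         drop_prob = 0) {
  if (strip_jitter_sd_px < 0) abort("`strip_jitter_sd_px` must be >= 0.")
  if (drop_prob < 0 || drop_prob > 1) abort("`drop_prob` must be in [0, 1].")
  structure(list(lateral_sd_px = lateral_sd_px, axial_sd_px = axial_sd_px,
                 strip_jitter_sd_px = strip_jitter_sd_px,
                 strip_width_px = strip_width_px, drop_prob = drop_prob),
            class = "motion_model")
}

#' Render a noisy multi-frame B-scan stack from contours
#'
#' Builds a piecewise-constant layer-intensity image from ground-truth
#' boundary contours, then emits `n_frames` copies, each translated by its
#' frame's true (integer, circular) lateral/axial shift, with optional
#' per-strip axial jitter and multiplicative gamma speckle (mean 1, SD
#' `noise_sd`). True shifts are stored alongside the frames so registration
#' accuracy can be audited exactly. Deterministic under a fixed seed.
#'
#' @param contours a `bscan_contours` object.
#' @param motion a [motion_model()].
#' @param n_frames number of frames (>= 1).
#' @param noise_sd speckle SD as a fraction of local intensity (0 = none).
#' @param seed RNG seed (required).
#' @param height_px image height; default fits the deepest boundary plus margin.
#' @param intensities named vector of region reflectivities.
#' @param texture_amp amplitude of a smooth fixed lateral reflectivity
#'   modulation applied to the retina (emulating vessel shadows and
#'   reflectivity texture that anchor lateral alignment in real scans;
#'   0 disables). The pattern is part of the scene: it translates with each
#'   frame's true shift.
#' @return an object of class `bscan_stack`: list with `frames`
#'   (n_frames x height x width array), `shifts` (tibble `frame`, `dy`, `dx`,
#'   `dropped`), `strip_shifts` (tibble `frame`, `strip`, `col_start`,
#'   `col_end`, `dy`), and `meta`.
#' @export
render_bscan_stack <- function(contours, motion = motion_model(),
                               n_frames = 40, noise_sd = 0.3, seed,
                               height_px = NULL,
                               intensities = c(vitreous = 0.06, RNFL = 0.80,
                                               GCL = 0.32, IPL = 0.55,
                                               INL_OPL = 0.42, OUTER = 0.68,
                                               below = 0.12),
                               texture_amp = 0.15) {
  stopifnot(inherits(contours, "bscan_contours"), n_frames >= 1)
  if (missing(seed)) abort("`seed` is required for stack rendering.")
  cb <- as.matrix(contours$contours[, boundary_names])
  width <- nrow(cb)
  height_px <- height_px %||% as.integer(ceiling(max(cb)) + 12L)
  base <- matrix(intensities[["below"]], nrow = height_px, ncol = width)
  region <- c("vitreous", "RNFL", "GCL", "IPL", "INL_OPL", "OUTER")
  rows <- seq_len(height_px) - 0.5
  for (j in seq_len(width)) {
    cuts <- c(-Inf, cb[j, ], Inf)
    idx <- findInterval(rows, cuts)  # 1 = vitreous ... 7 = below RPE
    vals <- c(intensities[region], intensities[["below"]])
    base[, j] <- vals[idx]
  }
  maxshift <- floor(min(height_px, width) / 3)
  with_seed(seed, {
    if (texture_amp > 0) {
      # smooth quasi-random lateral modulation, identical in every frame so
      # it translates with the scene
      u <- seq(0, 2 * pi, length.out = width)
      modul <- 1 + texture_amp * (
        sin(u * 5 + runif(1, 0, 2 * pi)) * 0.6 +
        sin(u * 11 + runif(1, 0, 2 * pi)) * 0.3 +
        sin(u * 23 + runif(1, 0, 2 * pi)) * 0.1)
      base <- sweep(base, 2, modul, `*`)
    }
    dys <- pmax(-maxshift, pmin(maxshift, round(rnorm(n_frames, 0, motion$axial_sd_px))))
    dxs <- pmax(-maxshift, pmin(maxshift, round(rnorm(n_frames, 0, motion$lateral_sd_px))))
    dropped <- runif(n_frames) < motion$drop_prob
    strips <- strip_bounds(width, motion$strip_width_px)
    frames <- array(0, dim = c(n_frames, height_px, width))
    strip_rows <- list()
    for (k in seq_len(n_frames)) {
      fr <- circshift2(base, dys[k], dxs[k])
      sdy <- integer(nrow(strips))
      if (motion$strip_jitter_sd_px > 0) {
        sdy <- pmax(-maxshift, pmin(maxshift,
          round(rnorm(nrow(strips), 0, motion$strip_jitter_sd_px))))
        for (s in seq_len(nrow(strips))) {
          if (sdy[s] != 0) {
            cols <- strips$col_start[s]:strips$col_end[s]
            fr[, cols] <- circshift2(fr[, cols, drop = FALSE], sdy[s], 0)
          }
        }
      }
      if (dropped[k]) fr <- matrix(mean(base), height_px, width)
      if (noise_sd > 0) {
        shape <- 1 / noise_sd^2
        fr <- fr * matrix(rgamma(length(fr), shape = shape, rate = shape),
                          height_px, width)
      }
      frames[k, , ] <- fr
      strip_rows[[k]] <- tibble(frame = k, strip = seq_len(nrow(strips)),
                                col_start = strips$col_start,
                                col_end = strips$col_end, dy = sdy)
    }
    structure(list(
      frames = frames,
      shifts = tibble(frame = seq_len(n_frames), dy = dys, dx = dxs,
                      dropped = dropped),
      strip_shifts = bind_rows(strip_rows),
      meta = c(contours$meta, list(n_frames = n_frames, noise_sd = noise_sd,
                                   height_px = height_px, seed = seed))
    ), class = "bscan_stack")
  })
}

# contiguous column blocks; a trailing strip narrower than min_width is
# merged into its neighbor
strip_bounds <- function(width, strip_width, min_width = 8L) {
  starts <- seq(1L, width, by = strip_width)
  ends <- pmin(starts + strip_width - 1L, width)
  if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)] + 1L) < min_width) {
    ends[length(ends) - 1L] <- ends[length(ends)]
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  tibble(strip = seq_along(starts), col_start = starts, col_end = ends)
}

#' Generate a synthetic study cohort
#'
#' Draws a control and an albinism group with demographics (age, sex,
#' per-eye axial length), per-participant phantom parameters, and a per-eye
#' scan inventory. Albinism nasal-side multipliers are drawn from a range
#' strictly above the control range, and a fraction of albinism participants
#' contribute one eye only. Ground-truth parameters are kept in the table so
#' downstream recovery can be audited. Seed-deterministic.
#'
#' @param n_control,n_albinism group sizes (>= 1).
#' @param seed RNG seed (required).
#' @param ranges parameter ranges, see [cohort_ranges()].
#' @return tibble with one row per participant: `participant`, `group`,
#'   `age`, `sex`, `al_od_mm`, `al_os_mm`, `has_od`, `has_os`, `rho_nt`,
#'   `rho_si`, `pit_scale`, `preset`.
#' @export
make_cohort <- function(n_control = 25, n_albinism = 30, seed,
                        ranges = cohort_ranges()) {
  if (missing(seed)) abort("`seed` is required for cohort generation.")
  if (n_control < 1 || n_albinism < 1) abort("Both groups must have >= 1 participant.")
  with_seed(seed, {
    draw_group <- function(n, group, r) {
      age <- round(pmin(r$age_max, pmax(r$age_min,
        rnorm(n, r$age_mean, r$age_sd))))
      al_od <- pmin(29, pmax(19, rnorm(n, r$al_mean, r$al_sd)))
      al_os <- pmin(29, pmax(19, al_od + rnorm(n, 0, 0.25)))
      rho_nt <- runif(n, r$rho_nt[1], r$rho_nt[2])
      rho_si <- runif(n, r$rho_si[1], r$rho_si[2])
      pit <- runif(n, r$pit_scale[1], r$pit_scale[2])
      single <- runif(n) < r$p_single_eye
      od_kept <- runif(n) < 0.5
      tibble(
        participant = sprintf("%s_%03d", toupper(substr(group, 1, 3)), seq_len(n)),
        group = group, age = age,
        sex = ifelse(runif(n) < r$p_female, "F", "M"),
        al_od_mm = round(al_od, 2), al_os_mm = round(al_os, 2),
        has_od = !single | od_kept, has_os = !single | !od_kept,
        rho_nt = rho_nt, rho_si = rho_si, pit_scale = pit,
        preset = cut(pit, c(-Inf, 0.1, 0.325, 0.575, 0.85, Inf),
                     labels = c("grade4", "grade3", "grade2", "grade1", "control"))
      )
    }
    out <- bind_rows(
      draw_group(n_control, "control", ranges$control),
      draw_group(n_albinism, "albinism", ranges$albinism)
    )
    out$preset <- as.character(out$preset)
    out
  })
}

#' Default cohort parameter ranges
#'
#' Age and axial-length distributions follow the demographics reported for
#' adult control and albinism OCT cohorts (control age 26.2 +/- 6.9 y, axial
#' length 24.08 +/- 1.05 mm; albinism age 24.3 +/- 11.9 y, axial length
#' 23.19 +/- 1.63 mm). Nasal-side multipliers are uniform ranges centered on
#' the groups' mean N:T GCL AUC ratios (1.20 control, 1.45 albinism), with
#' the albinism range strictly above the control range so group separation
#' is a generative fact that recovery tests can assert.
#'
#' @return nested list of ranges per group.
#' @export
cohort_ranges <- function() {
  list(
    control = list(
      age_mean = 26.2, age_sd = 6.9, age_min = 8, age_max = 60,
      al_mean = 24.08, al_sd = 1.05, p_female = 0.48,
      rho_nt = c(1.06, 1.34), rho_si = c(0.98, 1.14),
      pit_scale = c(1, 1), p_single_eye = 0
    ),
    albinism = list(
      age_mean = 24.3, age_sd = 11.9, age_min = 8, age_max = 60,
      al_mean = 23.19, al_sd = 1.63, p_female = 0.467,
      rho_nt = c(1.36, 1.54), rho_si = c(0.91, 1.07),
      pit_scale = c(0, 0.7), p_single_eye = 0.5
    )
  )
}

#' Phenotype for one cohort row
#'
#' @param row one row of a [make_cohort()] tibble.
#' @return a [fovea_phenotype()].
#' @export
cohort_phenotype <- function(row) {
  fovea_phenotype(preset = if (row$group == "control") "control" else "grade2",
                  rho_nt = row$rho_nt, rho_si = row$rho_si,
                  pit_scale = row$pit_scale)
}
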