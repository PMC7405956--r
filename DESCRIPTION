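Package: fovtopo
Title: Foveal Ganglion Cell Layer and Inner Plexiform Layer Topography from OCT Line Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify ganglion cell layer (GCL) and inner plexiform
    layer (IPL) topography at the fovea from optical coherence tomography
    (OCT) line scans. Implements multi-frame B-scan registration (global and
    strip-wise integer translation with normalized cross-correlation frame
    selection and averaging), boundary-contour-based layer thickness
    extraction with axial-length lateral rescaling, difference-of-Gaussians
    foveal pit localization, per-quadrant trapezoidal area-under-the-curve
    (AUC) and nasal:temporal / superior:inferior asymmetry metrics, and the
    accompanying statistical battery (Bland-Altman repeatability,
    D'Agostino-Pearson normality gating of t versus Mann-Whitney U tests,
    chi-square, seeded random eye selection). A synthetic foveal-phantom
    generator spanning the control-to-hypoplasia phenotype spectrum provides
    ground-truth contours, rendered speckled B-scan stacks with known motion,
    and closed-form oracles for every downstream metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
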