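---
title: "Methods: foveal GCL/IPL topography from OCT line scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foveal GCL/IPL topography from OCT line scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fovtopo)
```

# Scope and model

`fovtopo` quantifies the topography of the ganglion cell layer (GCL) and
inner plexiform layer (IPL) around the fovea from OCT line scans. The
analysis chain is: multi-frame B-scan registration and averaging, boundary
contours to physically scaled thickness profiles, foveal localization,
interpolation to a fixed eccentricity grid, per-quadrant area-under-the-curve
(AUC) and asymmetry ratios, and a group-statistics battery. Because clinical
scan sets of this kind are not publicly deposited, the package ships a
synthetic foveal phantom whose geometry, motion, and noise are fully known,
so that every downstream metric can be audited against a closed-form or
brute-force oracle.

## The generative phantom

Each retinal layer's half-profile is a baseline plus a difference of
Gaussians,

$$T(x) = \max\!\big(0,\; B - a_p e^{-x^2/2\sigma_p^2}
  + a_r e^{-x^2/2\sigma_r^2}\big),$$

with baseline $B$ (µm), a narrow pit of amplitude $a_p$ (µm) and width
$\sigma_p$ (mm), and a broad rim of amplitude $a_r$ (µm) and width
$\sigma_r$ (mm), constrained to $\sigma_p < \sigma_r$. This form was chosen
because it reproduces the pit-plus-rim morphology of inner retinal layers
and integrates in closed form over a quadrant via the error function, which
gives `analytic_quadrant_auc()` an exact oracle for the trapezoidal AUC
implementation. When a parameter set drives the expression negative the
profile is clamped at zero and flagged; the closed form then no longer
applies and the oracle falls back to adaptive quadrature.

Default layer parameters (µm / mm) describe a control morphology with a
fully excavated pit (GCL floor 8 µm at the fovea, maximum ≈ 45 µm near the
rim, parafoveal total retinal thickness ≈ 320 µm). The control GCL baseline
(30 µm) was set so that a symmetric control eye's four-quadrant summed GCL
AUC lands near 0.34 mm², the magnitude scale reported for adult control
cohorts. Hypoplasia presets `grade1`–`grade4` scale the pit amplitude by
0.7, 0.45, 0.2, and 0; `grade4` therefore shows essentially no foveal
depression, the hallmark of the least-developed incipient fovea.

### Asymmetry mechanism

Nasal–temporal (and superior–inferior) asymmetry is generated by a
multiplicative side factor: the whole one-sided profile is scaled by
$\rho_{NT}$ on the nasal half-axis ($\rho_{SI}$ superiorly on vertical
scans) and blended across the center with a logistic weight. Because the
factor is multiplicative, the nasal quadrant's closed-form AUC is exactly
$\rho$ times the temporal one, so the pipeline's measured N:T ratio should
recover $\rho$ — the package's central parameter-recovery audit.

The blend's transition (12%–88% of the weight) spans ±0.2 mm, i.e. a
logistic scale of 0.1 mm. The scale matters: blending mixes a little of
each side's mass across the fovea, biasing the measured ratio slightly
toward 1. At scale 0.1 mm the bias stays below 0.013 at $\rho = 1.45$
(within the 0.02 recovery tolerance the tests assert) because the pit floor
is thin where the mixing happens; a scale of 0.2 mm would roughly triple
that bias and make ratio recovery unreliable at realistic asymmetries.

One consequence worth knowing: applying $\rho$ to one side *adds* layer
mass, so a synthetic albinism eye with $\rho_{NT} = 1.45$ has a larger
summed AUC than a control eye. Real cohorts show similar summed AUC across
groups (mass is redistributed, not added). The phantom favors exact ratio
oracles over mass conservation; summed-AUC group contrasts on synthetic
cohorts are therefore phantom artifacts and are not treated as reference
values anywhere in the tests.

### Rendering, motion, and speckle

`render_bscan_stack()` paints a piecewise-constant reflectivity image from
the boundary stack (bright RNFL, dark GCL, brighter IPL, etc.), applies a
smooth fixed lateral reflectivity modulation (default amplitude 0.15)
emulating the vessel shadows and texture that anchor lateral alignment in
real B-scans, then emits frames shifted by integer per-frame lateral/axial
motion (defaults: SD 3 and 2 px), optional per-strip axial jitter
(nystagmus-scale intra-frame motion), and multiplicative gamma speckle with
mean 1 and SD 0.3 — a standard surrogate for fully developed OCT speckle.
Shifts are circular so that an exact inverse exists and registration
recovery can be asserted bit-exactly. All randomness flows from one
explicit seed per call; identical seeds give bit-identical stacks. The
scans' noise and motion statistics are conventions chosen to look like
mid-quality clinical line scans, not estimates fitted to any dataset.

### Synthetic cohorts

`make_cohort()` draws ages, sexes, and per-eye axial lengths from the
demographic distributions reported for adult control and albinism OCT
cohorts (control: 26.2 ± 6.9 y, AL 24.08 ± 1.05 mm, 48% female; albinism:
24.3 ± 11.9 y, AL 23.19 ± 1.63 mm, 46.7% female), and per-participant side
multipliers from uniform ranges centered on the groups' mean N:T GCL
ratios: control $\rho_{NT} \sim U[1.06, 1.34]$, albinism
$U[1.36, 1.54]$. The albinism range is deliberately strictly above the
control range (real distributions overlap) so that group separation is a
generative fact the recovery tests can assert; this makes the synthetic
group contrast a *calibration* check, not an effect-size estimate. Half the
albinism participants contribute one eye only, mirroring the reported scan
inventory structure.

## Registration

Frame alignment is integer-pixel translation at the argmax of the FFT
cross-correlation with a reference frame — translation dominates B-scan
motion, and integer shifts keep the phantom oracle exact. Sub-pixel spline
warping, rotation, and shear are deliberately out of scope. The reference
frame is an input (clinically it is chosen by hand); the default picks the
frame with maximal mean zero-lag NCC among 10 evenly sampled frames.

Strips are lateral blocks of 64 A-scan columns (a trailing strip narrower
than 8 columns merges into its neighbor), each re-aligned axially only,
since intra-frame motion in a B-scan is predominantly per-A-scan axial
drift. NCC is computed on mean-subtracted data over the mutually valid
region; regions a translation carries out of frame are masked, not
zero-filled. Selection ranks units by NCC, requires the 0.85 minimum, caps
the average at 30 units per pixel column (so parts of frames can enter),
and breaks NCC ties by frame index, making selection deterministic. If no
unit passes, the scan fails with an explicit `NO_FRAMES_PASS_NCC` error —
the analogue of excluding a scan for insufficient quality.

The registration audits run on rigid-motion stacks (per-strip jitter off),
because a per-frame "true shift" is only well defined when the frame moves
as a whole; jittered stacks exercise the strip path instead.

## Thickness, scaling, and the eccentricity grid

Lateral scale is the nominal scan length multiplied by the participant's
axial length over the scanner's assumed 24 mm, divided by 1000 A-scans
(e.g. a 7 mm scan in a 27.06 mm eye: 7.8925 µm per A-scan). The axial scale
(default 3.24 µm/px) comes from device metadata and is never recomputed
from image content. Thickness is the boundary separation times the axial
scale: TRT (ILM→RPE), GCL (RNFL/GCL→GCL/IPL), IPL (GCL/IPL→IPL/INL), GCIPL
(RNFL/GCL→IPL/INL); GCL + IPL = GCIPL holds to machine precision by
construction. No smoothing is applied to contours or profiles.

The foveal center of a control scan is the argmin (on a 1 µm grid) of a
difference-of-Gaussians fit to TRT, Levenberg–Marquardt with five starts at
the raw minimum ± {0, 0.2, 0.4} mm; non-convergence falls back to the raw
minimum with a flag. Scans without a reliable pit (the hypoplasia spectrum)
never use the fit; they take the mean of manual observer marks, with a
dispersion warning when marks disagree by more than 0.5 mm. A caveat the
tests make visible: under the phantom's *multiplicative* asymmetry the
TRT-minimum definition of the fovea sits slightly temporal to the blend
midpoint, so DoG-localized control scans read systematically lower N:T
ratios (~1.11 at generator mean 1.20) than truth-centered ones. This is a
property of the fovea definition interacting with the generative model, not
an implementation error; ratio-recovery audits therefore use the known
center, while cohort simulations accept the bias (it only widens the group
contrast).

Profiles are recentered with positive eccentricity nasal (horizontal) or
superior (vertical). Conventions, carried in metadata because scan
direction is device-specific: OD horizontal scans run image-left =
temporal; OS scans are mirrored so nasal stays positive; vertical scans run
image-left = inferior for both eyes. Mirroring an OS scan and relabeling
yields metrics identical to the OD geometry, which is tested.

Thickness is linearly interpolated at 100 µm steps over ±2.5 mm — exactly
51 samples, endpoints included; shorter coverage is an error (exclusion),
never extrapolation. Quadrant AUC is the trapezoid rule over the 26 samples
of one side, thickness converted to mm (AUC in mm²); the x = 0 sample
belongs to both quadrants, so the two quadrant AUCs sum exactly to the
full-width integral of the scan. Repeat segmentations are averaged
pointwise on the grid *before* AUC. The GCL-fraction profile is
100·GCL/GCIPL with GCIPL < 1 µm masked.

## Statistics

* **Bland–Altman**: bias ± 1.96 SD limits; CI of the bias from SD/√n, of
  each limit from √3·SD/√n, with t quantiles (n − 1 df).
* **Mann–Whitney U**: midranks; reported U = min(U₁, U₂) (consistent with
  printed magnitudes such as U = 279.5 for 25 vs 30); exact enumeration of
  all group assignments (valid under ties) when both n ≤ 8, otherwise the
  tie-corrected normal approximation without continuity correction — the
  convention that reproduces the printed p = 0.11 on the packaged age data.
* **t tests**: pooled-variance unpaired (df = n₁+n₂−2) and paired
  (df = n−1); zero-variance degeneracies return p = 1 (no difference) or
  p = 0 (certain difference), flagged.
* **Chi-square**: Yates-corrected on 2×2 counts — the correction is what
  reproduces the printed "P > 0.99" on the packaged sex counts.
* **D'Agostino–Pearson K²**: transformed skewness (D'Agostino 1970) plus
  transformed kurtosis (Anscombe–Glynn 1983) against χ²(2); implemented in
  the package because no installed R package provides the omnibus test; it
  is cross-checked against frozen reference values in the tests.
* **Gate**: both groups K²-normal (p > 0.05) *and* variances comparable
  (F test, α = 0.05, chosen because the decision rule mentions variance
  without naming a test) → unpaired t; otherwise Mann–Whitney. Groups with
  n < 8 cannot be normality-tested and fall back to Mann–Whitney, flagged.
  The gate record travels with every comparison so the path is auditable.
* **Eye selection**: one eye per participant, uniform and
  seed-deterministic; single-eye participants keep their eye. No
  mixed-effects modelling of eye-within-participant correlation is
  attempted (the eye-selection design handles it), and no multiple-testing
  correction is applied.

## Pipeline, problem sizes, and determinism

`run_pipeline()` chains cohort generation, per-scan repeat segmentations
(Gaussian boundary jitter, SD 0.5 px, emulating intra-observer segmentation
variability), foveal localization (DoG for controls — fitted once per scan
on the first segmentation — observer marks with 0.03 mm SD for albinism),
gridding, repeat averaging, quadrant metrics, seeded eye selection, and the
gated group tests, with every scan logged exactly once as included or
excluded with a coded reason (`SHORT_COVERAGE`, `NO_FRAMES_PASS_NCC`,
`ANALYSIS_ERROR`). Eyes whose axial length makes the scan physically
shorter than ±2.5 mm are carried as `SHORT_COVERAGE` exclusions, mirroring
the exclusion accounting of clinical cohorts. Everything is deterministic
under the config seed.

Simulation-based checks use deliberately moderate problem sizes, chosen as
a sensible audit scale for a laptop-class machine: cohort audits run 25-vs-30
participants at 300 A-scans per scan over 10–20 seeds; registration audits
use 256-column stacks of 8–40 frames over 20 seeds. The packaged
demographics tables are full-size.

## What the phantom does and does not show

Passing tests demonstrate that the *measurement chain* is correct: scales,
conventions, integrals, estimators, and decision rules do what they claim,
exactly where oracles exist. They do not demonstrate clinical validity on
real scans: the phantom has piecewise-constant reflectivity, no vasculature
or shadowing artifacts, no attenuation or signal roll-off, integer rigid
motion, gamma speckle rather than physical coherence speckle, and 2-D
cross-sections only (no volumes). Printed cohort values (summed AUC
0.341 mm², N:T GCL 1.45 vs 1.20, repeatability biases) derive from patient
scans that are not publicly available; the package treats them as magnitude
references and generator calibration points, never as reproduction targets.
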