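test_that("boundary ordering and layer additivity hold for every preset", {
  for (preset in c("control", "grade1", "grade2", "grade3", "grade4")) {
    for (rho in c(1, 1.45)) {
      ph <- fovea_phenotype(preset, rho_nt = rho, rho_si = 0.95)
      cc <- make_boundary_profiles(ph, n_ascans = 300)
      cb <- as.matrix(cc$contours[, c("ILM", "RNFL_GCL", "GCL_IPL",
                                      "IPL_INL", "OPL", "RPE")])
      expect_true(all(diff(t(cb)) >= -1e-9),
                  label = sprintf("ordering for %s rho=%g", preset, rho))
      tr <- tidyr::pivot_wider(cc$truth, names_from = "layer",
                               values_from = "thickness_um")
      expect_equal(tr$GCL + tr$IPL, tr$GCIPL)
      expect_equal(rowSums(tr[, c("RNFL", "GCL", "IPL", "INL_OPL", "OUTER")]),
                   tr$TRT, ignore_attr = TRUE)
    }
  }
})

test_that("symmetric control phantom is an even function with the expected pit floor", {
  ph <- fovea_phenotype("control")  # rho_nt = rho_si = 1
  cc <- make_boundary_profiles(ph, n_ascans = 301)  # odd -> exact center column
  gcl <- tidyr::pivot_wider(cc$truth, names_from = "layer",
                            values_from = "thickness_um")$GCL
  expect_equal(gcl, rev(gcl))
  p <- ph$layers[ph$layers$layer == "GCL", ]
  expect_equal(gcl[151], p$baseline_um - p$pit_amp_um + p$rim_amp_um)
})

test_that("grade-4 phantom shows essentially no foveal depression", {
  ph <- fovea_phenotype("grade4")
  expect_equal(ph$pit_scale, 0)
  x <- seq(-2.5, 2.5, by = 0.01)
  tt <- fovtopo:::phenotype_thickness(ph, x, "GCL")
  p <- ph$layers[ph$layers$layer == "GCL", ]
  # no pit: center equals baseline + rim; deviation from the edge value is
  # entirely the rim term
  expect_equal(tt[x == 0], p$baseline_um + p$rim_amp_um)
  rim_at_edge <- p$rim_amp_um * exp(-2.5^2 / (2 * p$rim_sigma_mm^2))
  expect_equal(tt[x == 0] - tt[x == 2.5], p$rim_amp_um - rim_at_edge,
               tolerance = 1e-10)
  expect_gt(min(tt), 0)
})

test_that("closed-form quadrant AUC matches adaptive quadrature to 1e-9", {
  # frozen quadrature value for B=100, a_p=80, s_p=0.3, a_r=30, s_r=1.0
  ph <- fovea_phenotype(layers = tibble::tibble(
    layer = c("RNFL", "GCL", "IPL", "INL_OPL", "OUTER"),
    baseline_um = c(100, 100, 100, 100, 100),
    pit_amp_um = c(0, 80, 0, 0, 0),
    pit_sigma_mm = c(0.3, 0.3, 0.3, 0.3, 0.3),
    rim_amp_um = c(0, 30, 0, 0, 0),
    rim_sigma_mm = c(1, 1, 1, 1, 1)
  ))
  expect_equal(as.numeric(analytic_quadrant_auc(ph, "GCL", "temporal")),
               0.257052925143, tolerance = 1e-9)
  # constant 100 um layer integrates to 0.25 mm^2
  expect_equal(as.numeric(analytic_quadrant_auc(ph, "RNFL", "nasal")), 0.25)
  # direct quadrature agreement across default layers and a rho factor
  ctrl <- fovea_phenotype("control", rho_nt = 1.3)
  for (ly in c("GCL", "IPL", "GCIPL")) {
    for (q in c("nasal", "temporal")) {
      rho <- if (q == "nasal") 1.3 else 1
      num <- 0
      for (l in if (ly == "GCIPL") c("GCL", "IPL") else ly) {
        p <- ctrl$layers[ctrl$layers$layer == l, ]
        num <- num + integrate(function(x) rho * fovtopo:::dog_thickness(x, p),
                               0, 2.5, rel.tol = 1e-12)$value / 1000
      }
      expect_equal(as.numeric(analytic_quadrant_auc(ctrl, ly, q)), num,
                   tolerance = 1e-9)
    }
  }
})

test_that("nasal AUC scales exactly linearly with the side multiplier", {
  ph1 <- fovea_phenotype("control", rho_nt = 1)
  ph2 <- fovea_phenotype("control", rho_nt = 1.2)
  expect_equal(as.numeric(analytic_quadrant_auc(ph2, "GCL", "nasal")),
               1.2 * as.numeric(analytic_quadrant_auc(ph1, "GCL", "temporal")))
  expect_equal(as.numeric(analytic_quadrant_auc(ph2, "GCL", "temporal")),
               as.numeric(analytic_quadrant_auc(ph1, "GCL", "temporal")))
})

test_that("clamped phenotypes fall back to numerical quadrature with a flag", {
  expect_warning(
    ph <- fovea_phenotype(layers = tibble::tibble(
      layer = c("RNFL", "GCL", "IPL", "INL_OPL", "OUTER"),
      baseline_um = c(50, 30, 50, 50, 100),
      pit_amp_um = c(0, 60, 0, 0, 0),   # pit deeper than baseline + rim
      pit_sigma_mm = rep(0.3, 5),
      rim_amp_um = c(0, 5, 0, 0, 0),
      rim_sigma_mm = rep(1, 5)
    )),
    "clamped"
  )
  auc <- analytic_quadrant_auc(ph, "GCL", "nasal")
  expect_true(attr(auc, "clamped"))
  p <- ph$layers[ph$layers$layer == "GCL", ]
  ref <- integrate(function(x) pmax(fovtopo:::dog_thickness(x, p), 0), 0, 2.5,
                   rel.tol = 1e-10)$value / 1000
  expect_equal(as.numeric(auc), ref, tolerance = 1e-8)
})

test_that("phenotype constructor rejects invalid Gaussian widths", {
  bad <- fovtopo:::phantom_layer_defaults()
  bad$pit_sigma_mm[2] <- 2  # wider than the rim
  expect_error(fovea_phenotype(layers = bad), "sigma_p")
  expect_error(fovea_phenotype(rho_nt = -0.1), "rho_nt")
})

test_that("grid too short to reach 2.5 mm is rejected", {
  ph <- default_phantom()
  expect_error(make_boundary_profiles(ph, n_ascans = 300, nominal_length_mm = 4),
               "2.5 mm")
})

test_that("rendered stacks are deterministic translations of the base frame", {
  ph <- default_phantom()
  cc <- make_boundary_profiles(ph, n_ascans = 200)
  still <- motion_model(lateral_sd_px = 0, axial_sd_px = 0,
                        strip_jitter_sd_px = 0)
  st0 <- render_bscan_stack(cc, still, n_frames = 4, noise_sd = 0, seed = 5)
  for (k in 2:4) expect_equal(st0$frames[k, , ], st0$frames[1, , ])
  # known shifts, zero noise: each frame is the circularly shifted base
  st <- render_bscan_stack(cc, motion_model(strip_jitter_sd_px = 0),
                           n_frames = 6, noise_sd = 0, seed = 6)
  base <- render_bscan_stack(cc, still, n_frames = 1, noise_sd = 0, seed = 6,
                             texture_amp = 0)$frames[1, , ]
  stb <- render_bscan_stack(cc, motion_model(strip_jitter_sd_px = 0),
                            n_frames = 6, noise_sd = 0, seed = 6,
                            texture_amp = 0)
  for (k in 1:6) {
    expect_equal(stb$frames[k, , ],
                 fovtopo:::circshift2(base, stb$shifts$dy[k], stb$shifts$dx[k]))
  }
  # determinism: same seed -> bit-identical
  st2 <- render_bscan_stack(cc, motion_model(), n_frames = 5, noise_sd = 0.3,
                            seed = 7)
  st3 <- render_bscan_stack(cc, motion_model(), n_frames = 5, noise_sd = 0.3,
                            seed = 7)
  expect_identical(st2$frames, st3$frames)
  expect_identical(st2$shifts, st3$shifts)
})

test_that("cohort generation is seed-deterministic with the requested structure", {
  co <- make_cohort(25, 30, seed = 7)
  expect_equal(nrow(co), 55)
  expect_equal(sum(co$group == "control"), 25)
  expect_equal(sum(co$group == "albinism"), 30)
  expect_identical(co, make_cohort(25, 30, seed = 7))
  r <- cohort_ranges()
  ctl <- co[co$group == "control", ]
  alb <- co[co$group == "albinism", ]
  expect_true(all(ctl$rho_nt >= r$control$rho_nt[1] &
                    ctl$rho_nt <= r$control$rho_nt[2]))
  expect_true(all(alb$rho_nt >= r$albinism$rho_nt[1] &
                    alb$rho_nt <= r$albinism$rho_nt[2]))
  # albinism range strictly above the control range
  expect_gt(min(alb$rho_nt), max(ctl$rho_nt))
  expect_true(all(ctl$has_od & ctl$has_os))
  expect_true(all(co$al_od_mm > 15 & co$al_od_mm < 35))
  expect_error(make_cohort(0, 5, seed = 1), ">= 1")
})
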