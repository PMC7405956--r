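make_test_stack <- function(n_frames = 8, noise_sd = 0, jitter = 0,
                            seed = 1, n_ascans = 256) {
  cc <- make_boundary_profiles(default_phantom(), n_ascans = n_ascans)
  render_bscan_stack(cc, motion_model(strip_jitter_sd_px = jitter),
                     n_frames = n_frames, noise_sd = noise_sd, seed = seed)
}

test_that("global registration recovers injected shifts exactly without noise", {
  st <- make_test_stack(n_frames = 8, noise_sd = 0, seed = 11)
  reg <- global_register(st, ref_index = 1)
  # recovered shifts are relative to the reference frame's true shift
  expect_equal(reg$frame_info$dy, st$shifts$dy - st$shifts$dy[1])
  expect_equal(reg$frame_info$dx, st$shifts$dx - st$shifts$dx[1])
  # reference vs itself: shift (0,0), NCC 1
  expect_equal(reg$frame_info$dy[1], 0L)
  expect_equal(reg$frame_info$dx[1], 0L)
  expect_equal(reg$frame_info$ncc[1], 1)
  expect_true(all(reg$frame_info$ncc > 0.999))
})

test_that("registration is shift-equivariant", {
  st <- make_test_stack(n_frames = 5, noise_sd = 0.2, seed = 12)
  reg1 <- global_register(st$frames, ref_index = 1)
  shifted <- st$frames
  for (k in 1:5) shifted[k, , ] <- fovtopo:::circshift2(st$frames[k, , ], 4, -6)
  reg2 <- global_register(shifted, ref_index = 1)
  expect_equal(reg2$frame_info$dy, reg1$frame_info$dy)
  expect_equal(reg2$frame_info$dx, reg1$frame_info$dx)
  for (k in 1:5) {
    expect_equal(reg2$frames[k, , ],
                 fovtopo:::circshift2(reg1$frames[k, , ], 4, -6))
  }
})

test_that("degenerate constant frames are flagged and excluded", {
  st <- make_test_stack(n_frames = 4, seed = 13)
  fr <- st$frames
  fr[3, , ] <- 0.5
  reg <- global_register(fr, ref_index = 1)
  expect_true(reg$frame_info$excluded[3])
  expect_true(is.na(reg$frame_info$ncc[3]))
  avg <- select_and_average(reg, threshold = 0.85)
  expect_equal(avg$report$reason[avg$report$frame == 3], "degenerate")
})

test_that("strip registration localizes single-strip axial jitter", {
  st <- make_test_stack(n_frames = 3, noise_sd = 0, seed = 14)
  reg <- global_register(st, ref_index = 1)
  fr <- reg$frames
  # inject +2 px axial jitter into strip 2 (columns 65-128) of frame 2
  fr[2, , 65:128] <- fovtopo:::circshift2(fr[2, , 65:128], 2, 0)
  reg$frames <- fr
  sr <- strip_register(reg, strip_width_px = 64)
  info <- sr$strip_info[sr$strip_info$frame == 2, ]
  expect_equal(info$dy[info$strip == 2], 2L)
  expect_true(all(info$dy[info$strip != 2] == 0L))
  expect_true(all(info$ncc > 0.999, na.rm = TRUE))
  # identical frame: all strips shift 0, NCC 1
  info3 <- sr$strip_info[sr$strip_info$frame == 3, ]
  expect_true(all(info3$dy == 0L))
  expect_true(all(info3$ncc > 0.999))
})

test_that("structureless strips score below the NCC threshold", {
  st <- make_test_stack(n_frames = 2, noise_sd = 0, seed = 15)
  reg <- global_register(st, ref_index = 1)
  set.seed(42)
  reg$frames[2, , 1:64] <- matrix(runif(64 * dim(reg$frames)[2]),
                                  dim(reg$frames)[2], 64)
  sr <- strip_register(reg, strip_width_px = 64)
  noisy <- sr$strip_info[sr$strip_info$frame == 2 & sr$strip_info$strip == 1, ]
  expect_lt(noisy$ncc, 0.85)
  avg <- select_and_average(sr, threshold = 0.85, unit = "strip")
  rep2 <- avg$report[avg$report$frame == 2 & avg$report$strip == 1, ]
  expect_equal(rep2$reason, "below_threshold")
})

test_that("selection keeps at most 30 units, threshold first, ties by frame index", {
  # synthetic registered stack with hand-set NCCs
  frames <- array(rep(1:3, each = 12), dim = c(3, 3, 4))
  reg <- structure(list(
    frames = frames,
    frame_info = tibble::tibble(frame = 1:3, dy = 0L, dx = 0L,
                                ncc = c(0.90, 0.84, 0.86), excluded = FALSE),
    ref_index = 1, meta = list()), class = "registered_stack")
  avg <- select_and_average(reg, threshold = 0.85, max_frames = 30)
  expect_equal(avg$report$frame[avg$report$included], c(1L, 3L))
  expect_equal(avg$report$reason[avg$report$frame == 2], "below_threshold")
  # exact cap: 40 identical frames all at NCC 1 -> exactly the first 30 kept
  frames40 <- array(1, dim = c(40, 3, 4))
  reg40 <- structure(list(
    frames = frames40,
    frame_info = tibble::tibble(frame = 1:40, dy = 0L, dx = 0L, ncc = 1,
                                excluded = FALSE),
    ref_index = 1, meta = list()), class = "registered_stack")
  avg40 <- select_and_average(reg40, threshold = 0.85, max_frames = 30)
  expect_equal(avg40$n_included, 30)
  expect_equal(sort(avg40$report$frame[avg40$report$included]), 1:30)
  expect_equal(avg40$image, frames40[1, , ])
  expect_true(all(avg40$coverage == 30))
  # nothing passes -> explicit failure
  regfail <- reg
  regfail$frame_info$ncc <- c(0.2, 0.3, 0.4)
  expect_error(select_and_average(regfail), "NO_FRAMES_PASS_NCC")
})

test_that("averaging identical frames reproduces a single frame", {
  cc <- make_boundary_profiles(default_phantom(), n_ascans = 200)
  still <- motion_model(lateral_sd_px = 0, axial_sd_px = 0,
                        strip_jitter_sd_px = 0)
  st <- render_bscan_stack(cc, still, n_frames = 5, noise_sd = 0, seed = 16)
  avg <- register_stack(st, ref_index = 1, strip_width_px = NULL)
  expect_equal(avg$image, st$frames[1, , ])
})

test_that("averaging denoises: averaged image beats every single frame", {
  cc <- make_boundary_profiles(default_phantom(), n_ascans = 200)
  clean <- render_bscan_stack(cc, motion_model(0, 0, 0), n_frames = 1,
                              noise_sd = 0, seed = 20,
                              texture_amp = 0)$frames[1, , ]
  wins <- 0
  for (s in 1:10) {
    st <- render_bscan_stack(cc, motion_model(0, 0, 0), n_frames = 8,
                             noise_sd = 0.3, seed = 20 + s, texture_amp = 0)
    reg <- global_register(st, ref_index = 1)
    avg <- select_and_average(reg, threshold = 0.2)
    ncc_avg <- cor(as.vector(avg$image), as.vector(clean))
    ncc_single <- max(sapply(1:8, function(k) {
      cor(as.vector(st$frames[k, , ]), as.vector(clean))
    }))
    if (ncc_avg > ncc_single) wins <- wins + 1
  }
  expect_equal(wins, 10)
})

test_that("automatic reference choice picks a representative frame", {
  st <- make_test_stack(n_frames = 10, noise_sd = 0.2, seed = 17)
  ref <- choose_reference(st)
  expect_true(ref %in% 1:10)
  fr <- st$frames
  fr[4, , ] <- 1  # constant frame can never be the reference
  expect_true(choose_reference(fr) != 4)
})
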