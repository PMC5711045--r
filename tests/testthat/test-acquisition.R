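test_that("angle schedule is uniform in angle and time with inclusive endpoints", {
  ff <- default_protocol("full_fan")
  s <- angle_schedule(ff)
  expect_equal(s$angle_deg[1], 0); expect_equal(s$time_s[1], 0)
  expect_equal(s$angle_deg[nrow(s)], 200)
  expect_equal(s$time_s[nrow(s)], 30)
  hf <- default_protocol("half_fan")
  sh <- angle_schedule(hf)
  expect_equal(unique(round(diff(sh$angle_deg), 10)),
               360 / (hf$n_projections - 1))
  # default scans cover at least 7 full periods of the 4 s default motion
  expect_gte(ff$duration_s / motion_period(0.25), 7)
})

test_that("central ray through a uniform cube integrates to mu times path", {
  n <- 40L
  vals <- array(0, c(n, n, n))
  vol <- voxel_volume(vals, spacing = 2)
  xs <- axis_coords(vol, 1)
  inside <- xs >= -25 & xs < 25
  vol$values[inside, inside, inside] <- 0.02
  prot <- scan_protocol("full_fan", arc_deg = 180, duration_s = 10,
                        n_projections = 2, panel_nu = 65, panel_nv = 65,
                        pitch_mm = 2)
  ps <- forward_project(vol, motion_pattern("static"), prot)
  expect_equal(ps$data[33, 33, 1], 1.0, tolerance = 0.005)  # 0.02/mm * 50 mm
})

test_that("all-zero volumes project to all-zero line integrals", {
  vol <- voxel_volume(array(0, c(16, 16, 16)), spacing = 4)
  prot <- scan_protocol("full_fan", arc_deg = 200, duration_s = 10,
                        n_projections = 3, panel_nu = 16, panel_nv = 16,
                        pitch_mm = 8)
  ps <- forward_project(vol, motion_pattern("static"), prot)
  expect_true(all(ps$data == 0))
})

test_that("projector matches a fine-step ray-sum oracle within 0.5%", {
  vol <- cached_phantom()
  prot <- scan_protocol("full_fan", arc_deg = 200, duration_s = 10,
                        n_projections = 3, panel_nu = 32, panel_nv = 32,
                        pitch_mm = 8)
  ps <- suppressWarnings(forward_project(vol, motion_pattern("static"), prot))
  for (a in 1:3) for (px in list(c(16, 16), c(12, 20), c(20, 13), c(10, 10))) {
    g <- det_pixel_geometry(prot, ps$angles_rad[a], px[1], px[2])
    oracle <- ray_integral_oracle(vol, g$src, g$dst, step = 0.05)
    got <- ps$data[px[1], px[2], a]
    if (oracle > 0.5)
      expect_lt(abs(got - oracle) / oracle, 0.005,
                label = sprintf("angle %d pixel (%d,%d): |%.4f - %.4f|/oracle",
                                a, px[1], px[2], got, oracle))
  }
})

test_that("projection is linear in the phantom", {
  set.seed(3)
  mk <- function() voxel_volume(array(runif(16^3, 0, 0.02), c(16, 16, 16)),
                                spacing = 4)
  a <- mk(); b <- mk()
  ab <- voxel_volume(a$values + b$values, spacing = 4)
  prot <- scan_protocol("full_fan", arc_deg = 200, duration_s = 10,
                        n_projections = 3, panel_nu = 24, panel_nv = 24,
                        pitch_mm = 6)
  st <- motion_pattern("static")
  expect_equal(forward_project(ab, st, prot)$data,
               forward_project(a, st, prot)$data +
                 forward_project(b, st, prot)$data,
               tolerance = 1e-10)
})

test_that("zero-amplitude motion reproduces the static acquisition bit-exactly", {
  vol <- voxel_volume(array(runif(12^3, 0, 0.02), c(12, 12, 12)), spacing = 4)
  prot <- scan_protocol("full_fan", arc_deg = 200, duration_s = 10,
                        n_projections = 4, panel_nu = 16, panel_nv = 16,
                        pitch_mm = 8)
  still <- motion_pattern("sinusoidal", A = 0, f = 0.25, phi = 1)
  expect_identical(forward_project(vol, still, prot)$data,
                   forward_project(vol, motion_pattern("static"), prot)$data)
})

test_that("static projections repeat after a full turn", {
  vol <- voxel_volume(array(runif(12^3, 0, 0.02), c(12, 12, 12)), spacing = 4)
  prot <- scan_protocol("half_fan", arc_deg = 360, duration_s = 10,
                        n_projections = 2, panel_nu = 24, panel_nv = 16,
                        pitch_mm = 8, lateral_offset_mm = 40)
  ps <- forward_project(vol, motion_pattern("static"), prot)
  expect_equal(ps$data[, , 1], ps$data[, , 2], tolerance = 1e-9)
})

test_that("Poisson noise is seeded, reproducible and vanishes at high flux", {
  vol <- cached_phantom()
  prot <- scan_protocol("full_fan", arc_deg = 200, duration_s = 10,
                        n_projections = 2, panel_nu = 24, panel_nv = 24,
                        pitch_mm = 8)
  ps <- suppressWarnings(forward_project(vol, motion_pattern("static"), prot))
  hi <- add_noise(ps, photons_per_ray = 1e12, seed = 5)
  expect_lt(max(abs(hi$data - ps$data)), 1e-4)
  expect_identical(add_noise(ps, 1e4, seed = 9)$data,
                   add_noise(ps, 1e4, seed = 9)$data)
  # flat-field variance ~ 1/photons
  flat <- ps; flat$data <- array(0, c(100, 100, 1))
  noisy <- add_noise(flat, photons_per_ray = 1000, seed = 1)
  expect_equal(stats::var(as.numeric(noisy$data)), 1 / 1000, tolerance = 0.05)
})
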