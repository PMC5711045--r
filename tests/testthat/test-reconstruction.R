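test_that("ramp filter reproduces the analytic Ram-Lak kernel", {
  du <- 1.5
  n <- 32L
  imp <- numeric(n); imp[17] <- 1
  out <- ramp_filter(imp, pitch = du)
  idx <- -4:4
  expected <- ifelse(idx == 0, 1 / (4 * du^2),
                     ifelse(idx %% 2 == 0, 0, -1 / (pi * idx * du)^2)) * du
  expect_equal(out[17 + idx], expected, tolerance = 1e-10)
})

test_that("ramp filter kills constants away from edges and is linear", {
  n <- 128L
  flat <- ramp_filter(rep(1, n), pitch = 1)
  peak <- 1 / 4  # impulse response maximum at du = 1
  expect_lt(max(abs(flat[33:96])), 0.05 * peak)
  # superposition: two impulses equal the sum of shifted kernels
  a <- numeric(n); a[40] <- 1
  b <- numeric(n); b[75] <- 2.5
  expect_equal(ramp_filter(a + b, pitch = 1),
               ramp_filter(a, pitch = 1) + ramp_filter(b, pitch = 1),
               tolerance = 1e-12)
})

test_that("occupancy blur conserves mass, dilates support by [-A, A]", {
  p <- motion_pattern("sinusoidal", A = 10, f = 0.25, phi = 0.4)
  # interior-support volume: the dilated support stays inside the grid
  tvals <- array(0, c(5, 5, 64))
  tvals[3, 3, 28:37] <- 1           # 10 voxels * 2 mm = 20 mm top-hat
  tvals[2, 4, 30:33] <- 0.4
  th <- voxel_volume(tvals, spacing = 2)
  bth <- occupancy_blur(th, p)
  expect_equal(sum(bth$values), sum(th$values), tolerance = 1e-9)
  # static is the identity
  vol <- cached_phantom()
  expect_identical(occupancy_blur(vol, motion_pattern("static"))$values,
                   vol$values)
  # support arithmetic on the top-hat column (L0 = 20, A = 10)
  k <- dwell_density(p, spacing = 2)
  nz <- which(bth$values[3, 3, ] > 0)
  expect_equal(length(nz), 10 + nrow(k) - 1)   # exact dilation
  expect_true(all(diff(nz) == 1))
  # refined sampling of the exact convolution: support width -> L0 + 2A
  fine <- occupancy_blur(th, p, z_refine = 8L)
  nzf <- which(fine$values[3, 3, ] > 1e-12)
  expect_lt(abs(length(nzf) * fine$spacing[3] - 40), 0.6)
})

test_that("FDK of zero projections is a zero volume", {
  prot <- scan_protocol("full_fan", arc_deg = 200, duration_s = 10,
                        n_projections = 5, panel_nu = 32, panel_nv = 32,
                        pitch_mm = 8)
  ps <- forward_project(voxel_volume(array(0, c(16, 16, 16)), spacing = 4),
                        motion_pattern("static"), prot)
  rec <- fdk_reconstruct(ps, grid = list(n = c(16, 16, 16), spacing = 4))
  expect_true(all(rec$values == 0))
})

test_that("static FDK reconstruction is quantitatively self-consistent", {
  cfg <- default_phantom_config()
  rec <- cached_static_recon("full_fan")
  vol <- cached_phantom()
  large <- cfg$targets[[3]]
  b <- target_bounds(large)
  ix <- which(axis_coords(rec, 1) > b["lo", 1] + 4 & axis_coords(rec, 1) < b["hi", 1] - 4)
  iy <- which(axis_coords(rec, 2) > b["lo", 2] + 4 & axis_coords(rec, 2) < b["hi", 2] - 4)
  iz <- which(axis_coords(rec, 3) > b["lo", 3] + 4 & axis_coords(rec, 3) < b["hi", 3] - 4)
  expect_equal(mean(rec$values[ix, iy, iz]), large$mu, tolerance = 0.1)
  # excess-attenuation centroid of the target region within one voxel of truth
  win <- expand.grid(x = axis_coords(rec, 1)[ix], y = axis_coords(rec, 2)[iy],
                     z = axis_coords(rec, 3)[iz])
  w <- as.numeric(rec$values[ix, iy, iz])
  centroid <- colSums(win * w) / sum(w)
  expect_lt(max(abs(centroid - large$center)), 2)
})

test_that("short or mismatched arcs are rejected", {
  prot <- scan_protocol("full_fan", arc_deg = 150, duration_s = 10,
                        n_projections = 5, panel_nu = 32, panel_nv = 32,
                        pitch_mm = 8)
  ps <- forward_project(voxel_volume(array(0, c(16, 16, 16)), spacing = 4),
                        motion_pattern("static"), prot)
  expect_error(fdk_reconstruct(ps, grid = list(n = c(16, 16, 16), spacing = 4)),
               "arc too short")
  proth <- scan_protocol("half_fan", arc_deg = 300, duration_s = 10,
                         n_projections = 5, panel_nu = 32, panel_nv = 32,
                         pitch_mm = 8, lateral_offset_mm = 40)
  psh <- forward_project(voxel_volume(array(0, c(16, 16, 16)), spacing = 4),
                         motion_pattern("static"), proth)
  expect_error(fdk_reconstruct(psh, grid = list(n = c(16, 16, 16), spacing = 4)),
               "full circle")
})

test_that("FDK of the moving phantom agrees with the occupancy-blur surrogate", {
  cfg <- default_phantom_config()
  p <- motion_pattern("sinusoidal", A = 10, f = 0.25, phi = 2.1)
  prot <- default_protocol("full_fan", desk_scale = TRUE)
  rec_moving <- fdk_reconstruct(forward_project(cached_phantom(), p, prot),
                                grid = cfg)
  rec_blur <- occupancy_blur(cached_static_recon("full_fan"), p)
  for (tg in cfg$targets) {
    zr <- z_window(tg, A = 10)
    m1 <- measure_length(rec_moving, tg, 0.1, z_range = zr)
    m2 <- measure_length(rec_blur, tg, 0.1, z_range = zr)
    expect_lt(abs(m1$length_mm - m2$length_mm), 2, label = tg$name)
  }
})
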