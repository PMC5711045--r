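test_that("phantom without targets contains only slab, foam and air values", {
  cfg <- phantom_config(grid = c(24, 24, 24), spacing = 4,
                        slab_halfwidth = 40, foam_halfheight = 16,
                        targets = list())
  vol <- build_phantom(cfg)
  expect_setequal(unique(as.numeric(vol$values)),
                  c(cfg$mu_air, cfg$mu_foam, cfg$mu_slab))
})

test_that("target z-extents rasterize to the exact voxel count", {
  cfg <- default_phantom_config()
  vol <- build_phantom(cfg)
  for (tg in cfg$targets) {
    prof <- target_axial_profile(vol, tg)
    # count within the target's own z range (targets can share a column)
    own <- abs(prof$z_mm - tg$center[3]) <= tg$extents[3] / 2 + vol$spacing[3]
    expect_equal(sum(prof$mu[own] == tg$mu), tg$extents[3] / vol$spacing[3],
                 info = tg$name)
  }
})

test_that("excess attenuation integral matches the analytic cuboid volumes", {
  cfg <- default_phantom_config()
  cfg0 <- phantom_config(targets = list())
  vol <- build_phantom(cfg); vol0 <- build_phantom(cfg0)
  vox <- prod(vol$spacing)
  got <- sum(vol$values - vol0$values) * vox
  expected <- sum(vapply(cfg$targets, function(t)
    prod(t$extents) * (t$mu - cfg$mu_foam), numeric(1)))
  # allow one boundary-voxel layer per face of each target
  slack <- sum(vapply(cfg$targets, function(t) {
    e <- t$extents
    2 * (e[1] * e[2] + e[1] * e[3] + e[2] * e[3]) * max(vol$spacing) *
      (t$mu - cfg$mu_foam)
  }, numeric(1)))
  expect_lt(abs(got - expected), slack)
})

test_that("voxelization is deterministic and boundary error halves with resolution", {
  cfg <- default_phantom_config()
  expect_identical(build_phantom(cfg)$values, build_phantom(cfg)$values)

  # worst-case z-extent error over sub-voxel target offsets, per spacing
  extent_err <- function(spacing) {
    max(vapply(seq(0, 1.9, by = 0.19), function(off) {
      tg <- target_spec("t", c(20, 20, 27), c(0, 0, off))
      cfg <- phantom_config(grid = c(16, 16, 48), spacing = c(4, 4, spacing),
                            slab_halfwidth = 28, foam_halfheight = 12,
                            targets = list(tg))
      vol <- build_phantom(cfg)
      prof <- target_axial_profile(vol, tg)
      abs(sum(prof$mu == tg$mu) * spacing - 27)
    }, numeric(1)))
  }
  e2 <- extent_err(2); e1 <- extent_err(1)
  expect_lte(e2, 2)          # never more than one voxel
  expect_lte(e1, 1)
  expect_lte(e1, e2 / 2 + 1e-9)
})

test_that("axial profile is a top-hat with the analytic excess integral", {
  cfg <- default_phantom_config()
  vol <- build_phantom(cfg)
  large <- cfg$targets[[3]]
  prof <- target_axial_profile(vol, large)
  inside <- prof$mu == large$mu
  expect_true(all(diff(which(inside)) == 1))  # contiguous top-hat
  expect_equal(sum(inside) * vol$spacing[3], 40)
  excess <- sum(prof$mu - cfg$mu_foam) * vol$spacing[3]
  expect_lt(abs(excess - (large$mu - cfg$mu_foam) * 40),
            vol$spacing[3] * (large$mu - cfg$mu_foam))

  # column through pure foam
  off <- target_spec("off", c(2, 2, 2), c(-45, 0, 0))
  prof2 <- target_axial_profile(vol, off)
  expect_true(all(prof2$mu == cfg$mu_foam))
})

test_that("invalid configurations are rejected", {
  t1 <- target_spec("a", c(20, 20, 20), c(0, 0, 0))
  t2 <- target_spec("b", c(20, 20, 20), c(5, 5, 5))
  expect_error(phantom_config(targets = list(t1, t2)), "overlap")
  expect_error(phantom_config(targets = list(
    target_spec("c", c(20, 80, 20), c(0, 0, 0)))), "outside the foam")
  expect_error(target_spec("d", c(-1, 2, 3), c(0, 0, 0)), "positive")
  vol <- build_phantom(default_phantom_config())
  expect_error(target_axial_profile(vol,
    target_spec("e", c(2, 2, 2), c(500, 0, 0))), "outside the grid")
})
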