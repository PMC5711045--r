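#' Target specification
#'
#' One cuboid water-equivalent target embedded in the lung-equivalent foam.
#' The z extent is the stationary length L0 along the superior-inferior
#' motion axis.
#'
#' @param name target label, conventionally `"small"`, `"medium"` or
#'   `"large"`.
#' @param extents length-3 numeric, full (x, y, z) edge lengths in mm.
#' @param center length-3 numeric, (x, y, z) centre in mm in the phantom
#'   frame (isocentre at the origin).
#' @param mu linear attenuation coefficient in 1/mm.
#' @return An object of class `target_spec`.
#' @examples
#' target_spec("large", extents = c(50, 30, 40), center = c(10, 0, 0))
#' @export
target_spec <- function(name, extents, center, mu = 0.020) {
  extents <- as.numeric(extents); center <- as.numeric(center)
  if (length(extents) != 3L || any(extents <= 0))
    stop("'extents' must be three positive lengths (mm)")
  if (length(center) != 3L) stop("'center' must be length 3")
  if (!is.numeric(mu) || mu <= 0) stop("'mu' must be positive")
  structure(list(name = as.character(name), extents = extents,
                 center = center, mu = mu),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("<target_spec> %s: %g x %g x %g mm at (%g, %g, %g), mu %g /mm\n",
              x$name, x$extents[1], x$extents[2], x$extents[3],
              x$center[1], x$center[2], x$center[3], x$mu))
  invisible(x)
}

target_bounds <- function(target) {
  rbind(lo = target$center - target$extents / 2,
        hi = target$center + target$extents / 2)
}

#' Phantom configuration
#'
#' Geometry and materials of the digital thorax phantom: a water-equivalent
#' slab block containing a lung-equivalent foam slab, with cuboid targets
#' inside the foam. Regions nest as target > foam > slab > air.
#'
#' @param grid integer length-3, voxel counts (nx, ny, nz).
#' @param spacing voxel spacing in mm (isotropic unless length 3). The
#'   default 2 mm matches a 2 mm reconstructed slice thickness.
#' @param mu_foam,mu_slab,mu_air linear attenuation coefficients (1/mm) of
#'   the lung-equivalent foam, the water-equivalent slabs and surrounding
#'   air.
#' @param slab_halfwidth half extent (mm) of the slab block in x and y.
#' @param foam_halfheight half extent (mm) of the foam slab in y (the foam
#'   spans the full slab in x and z).
#' @param targets list of [target_spec()] objects, mutually non-overlapping
#'   and inside the foam region.
#' @param supersample integer >= 1; per-axis subdivision used to
#'   antialias target boundaries. 1 (default) is pure centre-sampling and
#'   deterministic bit-for-bit.
#' @return An object of class `phantom_config`.
#' @seealso [default_phantom_config()] for the standard three-target setup.
#' @export
phantom_config <- function(grid = c(96, 96, 96), spacing = 2,
                           mu_foam = 0.005, mu_slab = 0.020, mu_air = 0,
                           slab_halfwidth = 80, foam_halfheight = 30,
                           targets = list(), supersample = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 2L)) stop("'grid' must be three counts >= 2")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("'spacing' must be positive")
  if (mu_air < 0 || mu_foam < 0 || mu_slab < 0) stop("attenuations must be >= 0")
  if (foam_halfheight > slab_halfwidth)
    stop("foam region must lie inside the slab region")
  half <- (grid - 1) / 2 * spacing
  if (slab_halfwidth > half[1] + spacing[1] / 2 ||
      slab_halfwidth > half[2] + spacing[2] / 2)
    stop("slab region must lie inside the grid")
  for (tg in targets) {
    if (!inherits(tg, "target_spec")) stop("'targets' must be target_spec objects")
    b <- target_bounds(tg)
    if (b["lo", 1] < -slab_halfwidth || b["hi", 1] > slab_halfwidth ||
        b["lo", 2] < -foam_halfheight || b["hi", 2] > foam_halfheight ||
        b["lo", 3] < -(half[3] + spacing[3] / 2) ||
        b["hi", 3] > half[3] + spacing[3] / 2)
      stop(sprintf("target '%s' extends outside the foam region", tg$name))
  }
  if (length(targets) > 1) {
    for (i in seq_len(length(targets) - 1)) for (j in (i + 1):length(targets)) {
      a <- target_bounds(targets[[i]]); b <- target_bounds(targets[[j]])
      if (all(a["lo", ] < b["hi", ] & b["lo", ] < a["hi", ]))
        stop(sprintf("targets '%s' and '%s' overlap",
                     targets[[i]]$name, targets[[j]]$name))
    }
  }
  structure(list(grid = grid, spacing = spacing, mu_foam = mu_foam,
                 mu_slab = mu_slab, mu_air = mu_air,
                 slab_halfwidth = slab_halfwidth,
                 foam_halfheight = foam_halfheight, targets = targets,
                 supersample = as.integer(supersample)),
            class = "phantom_config")
}

#' Default three-target thorax phantom
#'
#' Three water-equivalent cuboid targets (50 x 30 mm in cross section;
#' stationary lengths L0 = 10, 20 and 40 mm along z) in lung-equivalent foam
#' between water-equivalent slabs, on a 96^3 grid at 2 mm isotropic spacing.
#' The small target sits superior-right, the medium inferior-right and the
#' large medial-right, so all three remain inside both fan fields of view at
#' ranges of motion up to 40 mm.
#'
#' @param L0 stationary target lengths (mm) along z, named small/medium/large.
#' @param mu_target target attenuation (1/mm); water-equivalent gel.
#' @param ... passed on to [phantom_config()].
#' @return A [phantom_config()].
#' @examples
#' cfg <- default_phantom_config()
#' vapply(cfg$targets, function(t) t$extents[3], numeric(1))
#' @export
default_phantom_config <- function(L0 = c(small = 10, medium = 20, large = 40),
                                   mu_target = 0.020, ...) {
  targets <- list(
    target_spec("small",  c(50, 30, L0[["small"]]),  c(45, 0,  50), mu_target),
    target_spec("medium", c(50, 30, L0[["medium"]]), c(45, 0, -50), mu_target),
    target_spec("large",  c(50, 30, L0[["large"]]),  c(10, 0,   0), mu_target))
  phantom_config(targets = targets, ...)
}

#' Build the voxelized phantom
#'
#' Rasterizes a [phantom_config()] onto its grid. Each voxel takes the
#' attenuation of the innermost region containing the voxel centre
#' (target > foam > slab > air); intervals are half-open `[lo, hi)` so a
#' boundary that falls exactly on a voxel centre is assigned to one side
#' only. With `supersample > 1` each voxel is averaged over a regular
#' subgrid of sample points instead.
#'
#' @param config a [phantom_config()].
#' @return A [voxel_volume()] of linear attenuation coefficients, centred on
#'   the isocentre.
#' @examples
#' vol <- build_phantom(default_phantom_config())
#' range(vol$values)
#' @export
build_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$grid; sp <- config$spacing
  origin <- -(n - 1) / 2 * sp
  ss <- config$supersample
  if (ss == 1L) {
    offs <- list(0, 0, 0)
  } else {
    o <- (seq_len(ss) - (ss + 1) / 2) / ss
    offs <- list(o * sp[1], o * sp[2], o * sp[3])
  }
  acc <- array(0, n)
  for (ox in offs[[1]]) for (oy in offs[[2]]) for (oz in offs[[3]]) {
    xs <- origin[1] + (seq_len(n[1]) - 1) * sp[1] + ox
    ys <- origin[2] + (seq_len(n[2]) - 1) * sp[2] + oy
    zs <- origin[3] + (seq_len(n[3]) - 1) * sp[3] + oz
    vol <- array(config$mu_air, n)
    in_slab_x <- abs(xs) <= config$slab_halfwidth
    in_slab_y <- abs(ys) <= config$slab_halfwidth
    slab <- outer(outer(in_slab_x, in_slab_y, "&"), rep(TRUE, n[3]), "&")
    vol[slab] <- config$mu_slab
    in_foam_y <- abs(ys) <= config$foam_halfheight
    foam <- outer(outer(in_slab_x, in_foam_y, "&"), rep(TRUE, n[3]), "&")
    vol[foam] <- config$mu_foam
    for (tg in config$targets) {
      b <- target_bounds(tg)
      inx <- xs >= b["lo", 1] & xs < b["hi", 1]
      iny <- ys >= b["lo", 2] & ys < b["hi", 2]
      inz <- zs >= b["lo", 3] & zs < b["hi", 3]
      vol[outer(outer(inx, iny, "&"), inz, "&")] <- tg$mu
    }
    acc <- acc + vol
  }
  voxel_volume(acc / ss^3, spacing = sp, origin = origin)
}

#' Ground-truth axial profile through a target
#'
#' Extracts the attenuation values along z at the (x, y) voxel column
#' nearest the target centre, with the z coordinates in mm.
#'
#' @param volume a [voxel_volume()].
#' @param target a [target_spec()]; its centre must lie inside the grid.
#' @return A data frame with columns `z_mm` and `mu`.
#' @export
target_axial_profile <- function(volume, target) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(target, "target_spec"))
  d <- dim(volume$values)
  for (ax in 1:2) {
    lo <- volume$origin[ax]; hi <- volume$origin[ax] + (d[ax] - 1) * volume$spacing[ax]
    if (target$center[ax] < lo || target$center[ax] > hi)
      stop("target centre outside the grid")
  }
  ix <- nearest_index(volume, target$center[1], 1)
  iy <- nearest_index(volume, target$center[2], 2)
  data.frame(z_mm = axis_coords(volume, 3), mu = volume$values[ix, iy, ])
}
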