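# Independent oracles and shared (lazily cached) simulation fixtures.

# Trilinear interpolation at world points (n x 3 matrix, mm), written
# independently of the C++ sampler: vectorized corner-weight arithmetic.
trilinear_at <- function(vol, pts) {
  d <- dim(vol$values)
  idx <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
  out <- numeric(nrow(pts))
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
            idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
            idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!any(inside)) return(out)
  p <- idx[inside, , drop = FALSE]
  i0 <- pmin(floor(p), matrix(rep(d - 2, each = nrow(p)), ncol = 3))
  f <- p - i0
  acc <- numeric(nrow(p))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
         (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
         (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
    acc <- acc + w * vol$values[cbind(i0[, 1] + cx + 1, i0[, 2] + cy + 1,
                                      i0[, 3] + cz + 1)]
  }
  out[inside] <- acc
  out
}

# Brute-force fine-step ray sum from src to dst (world mm), step in mm.
ray_integral_oracle <- function(vol, src, dst, step = 0.05) {
  len <- sqrt(sum((dst - src)^2))
  n <- ceiling(len / step)
  t <- (seq_len(n) - 0.5) / n * len
  dirn <- (dst - src) / len
  pts <- cbind(src[1] + t * dirn[1], src[2] + t * dirn[2], src[3] + t * dirn[3])
  sum(trilinear_at(vol, pts)) * (len / n)
}

# Geometry of one detector pixel (1-based indices), re-derived from the
# protocol definition: source position and pixel world position at angle
# beta_rad.
det_pixel_geometry <- function(protocol, beta_rad, iu, iv) {
  cb <- cos(beta_rad); sb <- sin(beta_rad)
  src <- c(protocol$SAD * cb, protocol$SAD * sb, 0)
  u <- (iu - 1 - (protocol$panel_nu - 1) / 2) * protocol$pitch_mm +
    protocol$lateral_offset_mm
  v <- (iv - 1 - (protocol$panel_nv - 1) / 2) * protocol$pitch_mm
  dst <- c(-(protocol$SDD - protocol$SAD) * cb - u * sb,
           -(protocol$SDD - protocol$SAD) * sb + u * cb, v)
  list(src = src, dst = dst)
}

# Continuous arcsine-blurred top-hat profile: value at z of a unit-contrast
# target [-L0/2, L0/2] blurred by sinusoidal dwell density of amplitude A.
blurred_tophat <- function(z, L0, A) {
  Fcdf <- function(u) asin(pmin(pmax(u / A, -1), 1)) / pi + 0.5
  Fcdf(z + L0 / 2) - Fcdf(z - L0 / 2)
}

# Default z measurement window used across tests.
z_window <- function(target, A, margin = 8) {
  c(target$center[3] - target$extents[3] / 2 - A - margin,
    target$center[3] + target$extents[3] / 2 + A + margin)
}

# Lazily cached heavy simulations, shared across test files (test files run
# alphabetically; the acceptance file populates most of these first).
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) assign(key, fn(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

cached_phantom <- function() cached("phantom", function()
  build_phantom(default_phantom_config()))

cached_static_recon <- function(mode = "full_fan") {
  cached(paste0("static_", mode), function() {
    prot <- default_protocol(mode, desk_scale = TRUE)
    fdk_reconstruct(forward_project(cached_phantom(),
                                    motion_pattern("static"), prot),
                    grid = default_phantom_config())
  })
}

cached_fdk_sweep <- function() {
  cached("fdk_sweep", function()
    suppressWarnings(run_rom_sweep(engine = "fdk",
                                   modes = c("half_fan", "full_fan"),
                                   seed = 7L, desk_scale = TRUE)))
}

cached_surrogate_sweep <- function() {
  cached("surrogate_sweep", function()
    run_rom_sweep(engine = "surrogate", seed = 11L))
}
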