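#' Rigid one-dimensional motion pattern
#'
#' Trajectory of the phantom along the superior-inferior (z) axis.
#' Sinusoidal motion follows Z(t) = Zo + A sin(2 pi f t + phi), the standard
#' respiration surrogate; constant-speed motion follows Z(t) = Zo + Vp t;
#' static motion stays at Zo. The range of motion (ROM) is the peak-to-peak
#' excursion 2A.
#'
#' @param kind one of `"sinusoidal"`, `"constant"`, `"static"`.
#' @param A amplitude in mm (sinusoidal); ROM = 2A.
#' @param f frequency in Hz (sinusoidal). The default 0.25 Hz is 15 cycles
#'   per minute, i.e. a 4 s respiratory period.
#' @param phi phase in radians at t = 0.
#' @param Vp speed in mm/s (constant-speed motion).
#' @param Zo reference position in mm.
#' @return An object of class `motion_pattern`.
#' @examples
#' p <- motion_pattern("sinusoidal", A = 10)
#' displacement(p, seq(0, 4, by = 0.5))
#' @export
motion_pattern <- function(kind = c("sinusoidal", "constant", "static"),
                           A = 0, f = 0.25, phi = 0, Vp = 0, Zo = 0) {
  kind <- match.arg(kind)
  if (A < 0) stop("'A' must be >= 0")
  if (kind == "sinusoidal" && f <= 0) stop("'f' must be positive")
  if (kind == "static" && (A != 0 || Vp != 0))
    stop("a static pattern must have A = 0 and Vp = 0")
  structure(list(kind = kind, A = A, f = f, phi = phi, Vp = Vp, Zo = Zo),
            class = "motion_pattern")
}

#' @export
print.motion_pattern <- function(x, ...) {
  desc <- switch(x$kind,
    sinusoidal = sprintf("sinusoidal: A %g mm (ROM %g mm), f %g Hz, phi %.3f rad",
                         x$A, 2 * x$A, x$f, x$phi),
    constant   = sprintf("constant speed: Vp %g mm/s", x$Vp),
    static     = "static")
  cat(sprintf("<motion_pattern> %s; Zo %g mm\n", desc, x$Zo))
  invisible(x)
}

#' Displacement along z at time t
#'
#' Z(t) = Zo + A sin(2 pi f t + phi) for sinusoidal motion,
#' Zo + Vp t for constant speed, Zo for static.
#'
#' @param pattern a [motion_pattern()].
#' @param t time(s) in seconds, vectorized.
#' @return Displacement(s) in mm.
#' @export
displacement <- function(pattern, t) {
  stopifnot(inherits(pattern, "motion_pattern"))
  switch(pattern$kind,
    sinusoidal = pattern$Zo + pattern$A * sin(2 * pi * pattern$f * t + pattern$phi),
    constant   = pattern$Zo + pattern$Vp * t,
    static     = rep_len(pattern$Zo, length(t)))
}

#' Velocity along z at time t
#'
#' The time derivative of [displacement()]:
#' Vp(t) = 2 pi f A cos(2 pi f t + phi) for sinusoidal motion (peak speed
#' omega A), the constant Vp for constant-speed motion, 0 for static. With a
#' stationary couch this is also the target speed in the imaging frame.
#'
#' @inheritParams displacement
#' @return Velocity(-ies) in mm/s.
#' @export
velocity <- function(pattern, t) {
  stopifnot(inherits(pattern, "motion_pattern"))
  switch(pattern$kind,
    sinusoidal = 2 * pi * pattern$f * pattern$A *
      cos(2 * pi * pattern$f * t + pattern$phi),
    constant   = rep_len(pattern$Vp, length(t)),
    static     = rep_len(0, length(t)))
}

#' Dwell-time density of sinusoidal motion
#'
#' The fraction of time a sinusoidally moving point spends at each
#' displacement over a full period: the arcsine density
#' p(u) = 1 / (pi sqrt(A^2 - u^2)) on (-A, A), independent of frequency and
#' phase. Discretized by exact integration of the density over voxel-sized
#' bins centred on multiples of `spacing`, so the masses sum to 1 and the
#' support is exactly \[-A, A\] up to bin quantization. This kernel is what
#' a reconstruction of a scan much longer than the motion period images, and
#' it underlies [occupancy_blur()].
#'
#' @param pattern a sinusoidal (or static/degenerate A = 0)
#'   [motion_pattern()].
#' @param spacing bin width in mm, normally the volume's z spacing.
#' @return A data frame with columns `offset_mm` (bin centres) and `mass`
#'   (non-negative, summing to 1). A = 0 gives a single unit-mass bin at 0.
#' @examples
#' k <- dwell_density(motion_pattern("sinusoidal", A = 10), spacing = 2)
#' sum(k$mass)
#' @export
dwell_density <- function(pattern, spacing = 2) {
  stopifnot(inherits(pattern, "motion_pattern"))
  if (!pattern$kind %in% c("sinusoidal", "static"))
    stop("dwell_density is defined for sinusoidal (or static) patterns")
  A <- pattern$A
  if (A == 0)
    return(data.frame(offset_mm = 0, mass = 1))
  # CDF of the arcsine density, clamped to [-A, A]
  Fcdf <- function(u) {
    u <- pmin(pmax(u, -A), A)
    asin(u / A) / pi + 0.5
  }
  K <- ceiling(A / spacing + 0.5)
  centers <- seq(-K, K) * spacing
  mass <- Fcdf(centers + spacing / 2) - Fcdf(centers - spacing / 2)
  keep <- mass > 0
  data.frame(offset_mm = centers[keep], mass = mass[keep] / sum(mass[keep]))
}
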