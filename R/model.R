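#' Apparent length under constant-speed motion
#'
#' A target of stationary length L0 moving at constant speed Vp along the
#' scanner axis, with the couch stationary, appears elongated in the
#' reconstructed image: L = L0 + Vp * T, where T is the time the target
#' remains within the imaging view.
#'
#' @param L0 stationary length in mm (> 0).
#' @param Vp speed in mm/s (>= 0).
#' @param T_s in-view time in seconds (>= 0); typically the scan duration.
#' @return Apparent length in mm. Vectorized over any argument.
#' @examples
#' length_constant_speed(40, 1, 30)  # 70 mm
#' @export
length_constant_speed <- function(L0, Vp, T_s) {
  if (any(L0 <= 0)) stop("'L0' must be positive")
  if (any(Vp < 0)) stop("'Vp' must be >= 0")
  if (any(T_s < 0)) stop("'T_s' must be >= 0")
  L0 + Vp * T_s
}

#' Instantaneous apparent length under sinusoidal motion
#'
#' The time-varying form obtained by substituting the sinusoidal speed into
#' the constant-speed law: L(t) = L0 + \[2 pi f A cos(2 pi f t + phi)\] t.
#' Implemented exactly as written, with no clamping; the expression is
#' unbounded in t and can fall below L0 (or 0), so it is exposed for
#' inspection and plotting only. Quantitative comparisons in the experiment
#' drivers use [length_max_cyclic()] (cyclic motion) and
#' [length_constant_speed()] (constant speed) instead.
#'
#' @param L0 stationary length in mm (> 0).
#' @param A amplitude in mm (>= 0).
#' @param f frequency in Hz (> 0).
#' @param phi phase in radians.
#' @param t time in seconds (>= 0).
#' @return Length in mm (possibly < L0; see above).
#' @export
length_instantaneous <- function(L0, A, f, phi = 0, t) {
  if (any(L0 <= 0)) stop("'L0' must be positive")
  if (any(A < 0)) stop("'A' must be >= 0")
  if (any(f <= 0)) stop("'f' must be positive")
  if (any(t < 0)) stop("'t' must be >= 0")
  L0 + (2 * pi * f * A * cos(2 * pi * f * t + phi)) * t
}

#' Maximal apparent length under cyclic motion
#'
#' When the scan lasts longer than the motion period, every voxel of the
#' target sweeps the full excursion (-A, A) several times, so the target's
#' image occupies its stationary support dilated by the range of motion:
#' L = L0 + 2A, independent of the frequency and phase of the motion.
#'
#' @param L0 stationary length in mm (> 0).
#' @param A amplitude in mm (>= 0); ROM = 2A.
#' @param scan_duration_s,f optional scan duration (s) and motion frequency
#'   (Hz); if both are given and the scan is shorter than one period, a
#'   warning is issued (the long-scan regime is violated) but L0 + 2A is
#'   still returned.
#' @return Maximal apparent length in mm. Vectorized.
#' @examples
#' length_max_cyclic(40, 20)  # 80 mm at the largest studied amplitude
#' @export
length_max_cyclic <- function(L0, A, scan_duration_s = NULL, f = NULL) {
  if (any(L0 <= 0)) stop("'L0' must be positive")
  if (any(A < 0)) stop("'A' must be >= 0")
  if (!is.null(scan_duration_s) && !is.null(f) &&
      any(scan_duration_s < 1 / f))
    warning("scan shorter than one motion period: L0 + 2A is an upper bound")
  L0 + 2 * A
}

#' Motion period
#'
#' @param f frequency in Hz (> 0). 15 cycles/min = 0.25 Hz gives 4 s.
#' @return Period 1/f in seconds.
#' @examples
#' motion_period(15 / 60)  # 4
#' @export
motion_period <- function(f) {
  if (any(f <= 0)) stop("'f' must be positive")
  1 / f
}

#' Model prediction bundle
#'
#' Collects the closed-form predictions for one target and motion pattern:
#' the constant-speed length, the instantaneous-length function and the
#' cyclic maximum.
#'
#' @param L0 stationary length in mm.
#' @param pattern a [motion_pattern()].
#' @param T_s in-view scan time in seconds.
#' @return A list of class `model_prediction` with elements `L0`, `pattern`,
#'   `T_s`, `L_constant` (mm), `L_of_t` (function of t, mm) and `L_max` (mm).
#' @export
model_prediction <- function(L0, pattern, T_s = 30) {
  stopifnot(inherits(pattern, "motion_pattern"))
  Vp <- switch(pattern$kind,
    constant = pattern$Vp,
    sinusoidal = 2 * pi * pattern$f * pattern$A,
    static = 0)
  structure(list(
    L0 = L0, pattern = pattern, T_s = T_s,
    L_constant = length_constant_speed(L0, max(Vp, 0), T_s),
    L_of_t = if (pattern$kind == "sinusoidal")
      function(t) length_instantaneous(L0, pattern$A, pattern$f, pattern$phi, t)
    else function(t) length_constant_speed(L0, max(Vp, 0), t),
    L_max = if (pattern$kind == "sinusoidal")
      length_max_cyclic(L0, pattern$A) else L0),
    class = "model_prediction")
}
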