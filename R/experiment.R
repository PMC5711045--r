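# Measurement z-window for one target under a given amplitude: the blurred
# support plus a margin for the background tails.
target_z_window <- function(volume, target, A, margin = 8) {
  half <- target$extents[3] / 2 + A + margin
  z <- axis_coords(volume, 3)
  c(max(target$center[3] - half, min(z)),
    min(target$center[3] + half, max(z)))
}

measure_all_targets <- function(volume, config, A, threshold_fraction) {
  lapply(config$targets, function(tg)
    measure_length(volume, tg, threshold_fraction = threshold_fraction,
                   z_range = target_z_window(volume, tg, A)))
}

#' Range-of-motion sweep experiment
#'
#' Reproduces the core experiment: for each scan mode and each range of
#' motion (ROM = 2A, peak to peak), the phantom is moved sinusoidally at the
#' given frequency with a phase drawn from a seeded uniform distribution on
#' \[0, 2 pi) (the phase is deliberately not controlled), imaged, and the
#' apparent z-length of each target is measured and compared with the
#' cyclic-motion prediction L0 + ROM.
#'
#' Two engines are available: `"surrogate"` applies the arcsine
#' [occupancy_blur()] directly to the phantom (seconds for the whole sweep;
#' mode-independent, rows are labelled `"surrogate"`), `"fdk"` runs the full
#' projector + FDK chain per (mode, ROM). Elongation measurements default
#' to a low threshold fraction (0.05 surrogate, 0.1 FDK) because the
#' half-max crossing of a symmetric blur recovers the stationary length,
#' not the blurred support; see [measure_length()].
#'
#' @param config a [phantom_config()].
#' @param modes scan modes for the FDK engine, any of `"half_fan"`,
#'   `"full_fan"`.
#' @param roms ranges of motion in mm (peak to peak).
#' @param frequency motion frequency in Hz.
#' @param seed integer seed for the phase draws; the sweep is deterministic
#'   given the seed.
#' @param engine `"surrogate"` or `"fdk"`.
#' @param threshold_fraction measurement threshold; NULL picks the engine
#'   default above.
#' @param desk_scale use the reduced scan presets (FDK engine).
#' @param filter_window passed to [fdk_reconstruct()].
#' @return A data frame of class `experiment_result`, one row per
#'   (mode, ROM, target): columns `mode`, `rom_mm`, `frequency_hz`,
#'   `phase_rad`, `seed`, `target`, `L0_mm`, `measured_mm`, `predicted_mm`
#'   (= L0 + ROM), `deviation_mm` and `flags`.
#' @examples
#' \donttest{
#' res <- run_rom_sweep(engine = "surrogate", roms = c(0, 10, 20), seed = 1)
#' res[, c("rom_mm", "target", "measured_mm", "predicted_mm")]
#' }
#' @export
run_rom_sweep <- function(config = default_phantom_config(),
                          modes = c("half_fan", "full_fan"),
                          roms = c(0, 5, 10, 15, 20, 25, 30, 40),
                          frequency = 0.25, seed = 1L,
                          engine = c("surrogate", "fdk"),
                          threshold_fraction = NULL, desk_scale = TRUE,
                          filter_window = "hann") {
  stopifnot(inherits(config, "phantom_config"))
  if (any(roms < 0)) stop("'roms' must be >= 0")
  engine <- match.arg(engine)
  if (is.null(threshold_fraction))
    threshold_fraction <- if (engine == "surrogate") 0.05 else 0.1
  if (engine == "surrogate") modes <- "surrogate"
  static_vol <- build_phantom(config)
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
  set.seed(seed)
  # one uncontrolled phase per ROM, shared by both scan modes so that the
  # half-fan/full-fan comparison sees the same motion pattern
  phases <- stats::runif(length(roms), 0, 2 * pi)
  rows <- list()
  for (mi in seq_along(modes)) for (ri in seq_along(roms)) {
    rom <- roms[ri]; A <- rom / 2; phi <- phases[ri]
    pattern <- if (A > 0)
      motion_pattern("sinusoidal", A = A, f = frequency, phi = phi)
    else motion_pattern("static")
    vol <- tryCatch({
      if (engine == "surrogate") {
        # refined z sampling of the exact convolution: sub-voxel crossings
        occupancy_blur(static_vol, pattern, z_refine = 8L)
      } else {
        prot <- default_protocol(modes[mi], desk_scale = desk_scale)
        fdk_reconstruct(forward_project(static_vol, pattern, prot),
                        grid = config, filter_window = filter_window)
      }
    }, error = function(e)
      stop(sprintf("[mode %s, ROM %g mm] %s", modes[mi], rom,
                   conditionMessage(e)), call. = FALSE))
    ms <- measure_all_targets(vol, config, A, threshold_fraction)
    for (m in ms) {
      L0 <- config$targets[[match(m$target, vapply(config$targets,
                                                   `[[`, "", "name"))]]$extents[3]
      rows[[length(rows) + 1]] <- data.frame(
        mode = modes[mi], rom_mm = rom, frequency_hz = frequency,
        phase_rad = phi, seed = seed, target = m$target, L0_mm = L0,
        measured_mm = m$length_mm,
        predicted_mm = length_max_cyclic(L0, A),
        deviation_mm = m$length_mm - length_max_cyclic(L0, A),
        flags = paste(m$flags, collapse = ","))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_result", class(out))
  attr(out, "engine") <- engine
  attr(out, "threshold_fraction") <- threshold_fraction
  out
}

#' Constant-speed length curve
#'
#' Evaluates the constant-speed law L = L0 + Vp T on a grid of speeds for
#' each target length, giving the three parallel model lines (slope T mm
#' per mm/s, intercepts L0). Optionally validates one speed by simulating a
#' full constant-speed acquisition of the large target and measuring its
#' apparent length.
#'
#' @param L0_list stationary lengths in mm.
#' @param speeds speeds in mm/s (>= 0).
#' @param T_s imaging time in seconds.
#' @param validate_vp optional single speed (mm/s) to validate by
#'   simulation; uses a full-fan scan of duration `T_s`.
#' @param config phantom for the validation run.
#' @param desk_scale use the reduced preset for the validation run.
#' @return A data frame with columns `L0_mm`, `speed_mm_s`, `predicted_mm`
#'   and, for the validated speed, `measured_mm` (NA elsewhere). The
#'   validation measures the large (longest-L0) target.
#' @export
run_speed_curve <- function(L0_list = c(small = 10, medium = 20, large = 40),
                            speeds = seq(0, 2, by = 0.25), T_s = 30,
                            validate_vp = NULL,
                            config = default_phantom_config(),
                            desk_scale = TRUE) {
  if (any(speeds < 0)) stop("'speeds' must be >= 0")
  if (T_s <= 0) stop("'T_s' must be positive")
  tab <- expand.grid(L0_mm = as.numeric(L0_list), speed_mm_s = speeds,
                     KEEP.OUT.ATTRS = FALSE)
  tab$predicted_mm <- length_constant_speed(tab$L0_mm, tab$speed_mm_s, T_s)
  tab$measured_mm <- NA_real_
  if (!is.null(validate_vp)) {
    stopifnot(length(validate_vp) == 1L, validate_vp >= 0)
    prot <- default_protocol("full_fan", desk_scale = desk_scale)
    prot$duration_s <- T_s
    pattern <- if (validate_vp > 0)
      motion_pattern("constant", Vp = validate_vp)
    else motion_pattern("static")
    tgt <- config$targets[[which.max(vapply(config$targets,
                                            function(t) t$extents[3], 0))]]
    # image the measured target alone: unlike cyclic motion, constant speed
    # never revisits a position, so each transient position is seen over a
    # sub-arc only and the other targets would cast limited-angle ghosts
    # across the profile
    solo <- config; solo$targets <- list(tgt)
    vol <- fdk_reconstruct(forward_project(build_phantom(solo), pattern,
                                           prot), grid = config)
    win <- c(tgt$center[3] - tgt$extents[3] / 2 - 8,
             tgt$center[3] + tgt$extents[3] / 2 + validate_vp * T_s + 8)
    m <- measure_length(vol, tgt, threshold_fraction = 0.05, z_range = win)
    sel <- tab$L0_mm == tgt$extents[3] &
      abs(tab$speed_mm_s - validate_vp) < 1e-9
    if (!any(sel)) {
      tab <- rbind(tab, data.frame(
        L0_mm = tgt$extents[3], speed_mm_s = validate_vp,
        predicted_mm = length_constant_speed(tgt$extents[3], validate_vp, T_s),
        measured_mm = m$length_mm))
    } else {
      tab$measured_mm[sel] <- m$length_mm
    }
  }
  tab
}

#' Compare half-fan and full-fan measured lengths
#'
#' Per (ROM, target) absolute difference of the measured apparent lengths
#' between the two scan modes.
#'
#' @param result an `experiment_result` from [run_rom_sweep()] run with both
#'   `"half_fan"` and `"full_fan"` modes (FDK engine).
#' @return A data frame with columns `rom_mm`, `target`, `half_fan_mm`,
#'   `full_fan_mm` and `abs_diff_mm`.
#' @export
compare_modes <- function(result) {
  stopifnot(is.data.frame(result))
  if (!all(c("half_fan", "full_fan") %in% unique(result$mode)))
    stop("'result' must contain both half_fan and full_fan rows")
  hf <- result[result$mode == "half_fan", ]
  ff <- result[result$mode == "full_fan", ]
  key <- c("rom_mm", "target")
  mg <- merge(hf[, c(key, "measured_mm")], ff[, c(key, "measured_mm")],
              by = key, suffixes = c("_hf", "_ff"))
  data.frame(rom_mm = mg$rom_mm, target = mg$target,
             half_fan_mm = mg$measured_mm_hf, full_fan_mm = mg$measured_mm_ff,
             abs_diff_mm = abs(mg$measured_mm_hf - mg$measured_mm_ff))
}
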