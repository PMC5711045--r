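#' Scan protocol
#'
#' Gantry arc, timing and cone-beam geometry for one CBCT acquisition.
#' Half-fan mode laterally displaces the detector and scans a full circle
#' (enlarged field of view); full-fan centres the detector and uses a
#' short-scan arc of roughly half a circle. kVp and mAs are carried as
#' metadata only; the simulation is geometric.
#'
#' @param mode `"half_fan"` or `"full_fan"`.
#' @param arc_deg gantry arc in degrees (0 < arc <= 360).
#' @param duration_s scan duration in seconds.
#' @param n_projections number of projections (>= 2), uniform in angle and
#'   time.
#' @param SAD,SDD source-axis and source-detector distances in mm
#'   (SDD > SAD > 0).
#' @param panel_nu,panel_nv detector pixel counts (u = fan direction,
#'   v = axial).
#' @param pitch_mm detector pixel pitch in mm.
#' @param lateral_offset_mm detector displacement along u in mm; must be 0
#'   in full-fan mode.
#' @param kVp,mAs tube metadata (not used by the physics).
#' @return An object of class `scan_protocol`.
#' @seealso [default_protocol()] for the standard and desk-scale presets.
#' @export
scan_protocol <- function(mode = c("half_fan", "full_fan"), arc_deg,
                          duration_s, n_projections, SAD = 1000, SDD = 1500,
                          panel_nu = 128, panel_nv = 128, pitch_mm = 3,
                          lateral_offset_mm = 0, kVp = NA_real_,
                          mAs = NA_real_) {
  mode <- match.arg(mode)
  if (arc_deg <= 0 || arc_deg > 360) stop("'arc_deg' must be in (0, 360]")
  if (n_projections < 2) stop("'n_projections' must be >= 2")
  if (!(SDD > SAD && SAD > 0)) stop("need SDD > SAD > 0")
  if (duration_s <= 0) stop("'duration_s' must be positive")
  if (mode == "full_fan" && lateral_offset_mm != 0)
    stop("'lateral_offset_mm' must be 0 in full-fan mode")
  structure(list(mode = mode, arc_deg = arc_deg, duration_s = duration_s,
                 n_projections = as.integer(n_projections), SAD = SAD,
                 SDD = SDD, panel_nu = as.integer(panel_nu),
                 panel_nv = as.integer(panel_nv), pitch_mm = pitch_mm,
                 lateral_offset_mm = lateral_offset_mm, kVp = kVp, mAs = mAs),
            class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    "<scan_protocol> %s: %g deg arc, %g s, %d projections\n",
    x$mode, x$arc_deg, x$duration_s, x$n_projections))
  cat(sprintf("  SAD %g / SDD %g mm; panel %d x %d @ %g mm, offset %g mm\n",
              x$SAD, x$SDD, x$panel_nu, x$panel_nv, x$pitch_mm,
              x$lateral_offset_mm))
  invisible(x)
}

#' Default scan protocols
#'
#' Half-fan: full 360 degree circle in 60 s (thorax-style technique,
#' 125 kVp / 264 mAs metadata), displaced detector. Full-fan: 200 degree
#' short scan (180 degrees plus fan angle, with margin) in 30 s (head-style
#' technique, 100 kVp / 146 mAs metadata), centred detector. The geometry is
#' a generic on-board imager: SAD 1000 mm, SDD 1500 mm, 384 mm square panel,
#' half-fan lateral offset 143 mm (the conventional 37% of the panel width).
#' `desk_scale = TRUE` halves the projection count and coarsens the panel to
#' 96 x 96 at 4 mm pitch (same physical size) to keep simulations fast.
#'
#' @param mode `"half_fan"` or `"full_fan"`.
#' @param desk_scale logical; use the reduced preset.
#' @return A [scan_protocol()].
#' @examples
#' default_protocol("full_fan")
#' @export
default_protocol <- function(mode = c("half_fan", "full_fan"),
                             desk_scale = FALSE) {
  mode <- match.arg(mode)
  full <- list(
    half_fan = list(arc = 360, dur = 60, np = 360L, kVp = 125, mAs = 264,
                    off = 143),
    full_fan = list(arc = 200, dur = 30, np = 200L, kVp = 100, mAs = 146,
                    off = 0))[[mode]]
  np <- if (desk_scale) full$np %/% 2L else full$np
  nuv <- if (desk_scale) 96L else 128L
  pitch <- if (desk_scale) 4 else 3
  scan_protocol(mode, arc_deg = full$arc, duration_s = full$dur,
                n_projections = np, panel_nu = nuv, panel_nv = nuv,
                pitch_mm = pitch, lateral_offset_mm = full$off,
                kVp = full$kVp, mAs = full$mAs)
}

#' Angle and time schedule of a protocol
#'
#' Gantry angles uniform over the arc and timestamps uniform over the scan
#' duration, both inclusive of the endpoints (angular step
#' arc/(n-1)). Deterministic.
#'
#' @param protocol a [scan_protocol()].
#' @return A data frame with columns `index`, `angle_deg` and `time_s`.
#' @examples
#' head(angle_schedule(default_protocol("full_fan")))
#' @export
angle_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  n <- protocol$n_projections
  data.frame(index = seq_len(n),
             angle_deg = seq(0, protocol$arc_deg, length.out = n),
             time_s = seq(0, protocol$duration_s, length.out = n))
}

#' Simulate a time-resolved cone-beam acquisition
#'
#' For each projection the phantom is rigidly displaced along z by the
#' motion pattern evaluated at the projection timestamp (applied as a shift
#' of the sampling grid, exact for rigid 1D motion), and cone-beam line
#' integrals are computed from the source to every detector pixel by ray
#' marching with trilinear interpolation.
#'
#' @param volume the static phantom, a [voxel_volume()].
#' @param pattern a [motion_pattern()]; displacement relative to the
#'   reference position Zo is applied.
#' @param protocol a [scan_protocol()].
#' @param step ray-marching step in mm; defaults to half the smallest voxel
#'   spacing.
#' @return An object of class `projection_set`: list with `data` (array
#'   nu x nv x n of line integrals), `angles_rad`, `times_s`, `protocol`,
#'   and `provenance` (warnings such as a target leaving the field of view).
#' @export
forward_project <- function(volume, pattern, protocol, step = NULL) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(pattern, "motion_pattern"),
            inherits(protocol, "scan_protocol"))
  if (any(is.na(volume$values))) stop("volume contains NaN")
  if (is.null(step)) step <- min(volume$spacing) / 2
  sched <- angle_schedule(protocol)
  zshift <- displacement(pattern, sched$time_s) - pattern$Zo
  prov <- character()
  # in-view check: the displaced object support must stay inside the cone
  occ <- which(volume$values > 0, arr.ind = TRUE)
  if (nrow(occ) == 0) occ <- matrix(1L, 1, 3)
  zmax <- max(abs(axis_coords(volume, 3)[range(occ[, 3])])) +
    max(abs(zshift))
  rmax <- sqrt(max(abs(axis_coords(volume, 1)[range(occ[, 1])]))^2 +
                 max(abs(axis_coords(volume, 2)[range(occ[, 2])]))^2)
  v_half_iso <- (protocol$panel_nv - 1) / 2 * protocol$pitch_mm *
    protocol$SAD / protocol$SDD
  if (zmax > v_half_iso * (protocol$SAD - rmax) / protocol$SAD) {
    msg <- "phantom may leave the axial field of view at peak displacement"
    warning(msg)
    prov <- c(prov, msg)
  }
  proj <- cpp_forward_project(
    as.numeric(volume$values), dim(volume$values), volume$spacing,
    volume$origin, sched$angle_deg * pi / 180, zshift, protocol$SAD,
    protocol$SDD, protocol$panel_nu, protocol$panel_nv, protocol$pitch_mm,
    protocol$pitch_mm, protocol$lateral_offset_mm, step)
  structure(list(data = proj, angles_rad = sched$angle_deg * pi / 180,
                 times_s = sched$time_s, protocol = protocol,
                 provenance = prov),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<projection_set> %d projections of %d x %d pixels (%s)\n",
              d[3], d[1], d[2], x$protocol$mode))
  cat(sprintf("  arc %g deg over %g s; line integrals in [%.3g, %.3g]\n",
              x$protocol$arc_deg, x$protocol$duration_s,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Add transmission-domain Poisson noise
#'
#' Converts line integrals p to expected photon counts N exp(-p), draws
#' Poisson counts, and re-logs. Counts are floored at 1 photon before the
#' log. Off by default in every pipeline: the elongation analysis is
#' geometric.
#'
#' @param projections a `projection_set`.
#' @param photons_per_ray unattenuated photons per detector pixel (> 0).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return A new `projection_set` with noisy line integrals.
#' @export
add_noise <- function(projections, photons_per_ray, seed = 1L) {
  stopifnot(inherits(projections, "projection_set"))
  if (photons_per_ray <= 0) stop("'photons_per_ray' must be positive")
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
  set.seed(seed)
  counts <- stats::rpois(length(projections$data),
                         photons_per_ray * exp(-projections$data))
  noisy <- -log(pmax(counts, 1) / photons_per_ray)
  projections$data <- array(noisy, dim(projections$data))
  projections
}

#' Write projections and their schedule to disk
#'
#' The projection stack goes to a NIfTI file (u, v, projection index) and
#' the per-projection schedule to a CSV sidecar with columns `index`,
#' `angle_deg` and `time_s`.
#'
#' @param projections a `projection_set`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>_schedule.csv`.
#' @return The two paths, invisibly.
#' @export
write_projections <- function(projections, prefix) {
  stopifnot(inherits(projections, "projection_set"))
  nii <- paste0(prefix, ".nii.gz")
  csv <- paste0(prefix, "_schedule.csv")
  RNifti::writeNifti(RNifti::asNifti(projections$data), nii)
  utils::write.csv(data.frame(index = seq_along(projections$angles_rad),
                              angle_deg = projections$angles_rad * 180 / pi,
                              time_s = projections$times_s),
                   csv, row.names = FALSE)
  invisible(c(nii, csv))
}
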