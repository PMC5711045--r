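#' Read a simulation configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) file describing the phantom,
#' the motion pattern and/or the scan protocol, and returns the
#' corresponding objects. All sections are optional; omitted fields fall
#' back to the package defaults, so an empty file yields the default study
#' setup.
#'
#' Recognized sections:
#' \describe{
#'   \item{phantom}{`grid`, `spacing`, `mu_foam`, `mu_slab`, `mu_air`,
#'     `slab_halfwidth`, `foam_halfheight`, and `targets`: a list of
#'     `{name, extents, center, mu}` entries.}
#'   \item{motion}{`kind`, `A`, `f`, `phi`, `Vp`, `Zo`.}
#'   \item{protocol}{`mode`, `desk_scale`, plus any [scan_protocol()]
#'     override (`arc_deg`, `duration_s`, `n_projections`, ...).}
#' }
#'
#' @param path YAML file path.
#' @return A list with elements `phantom` ([phantom_config()]), `motion`
#'   ([motion_pattern()]) and `protocol` ([scan_protocol()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  ph <- raw$phantom
  phantom <- if (is.null(ph)) {
    default_phantom_config()
  } else {
    targets <- if (is.null(ph$targets)) {
      default_phantom_config()$targets
    } else {
      lapply(ph$targets, function(t)
        target_spec(t$name, unlist(t$extents), unlist(t$center),
                    if (is.null(t$mu)) 0.020 else t$mu))
    }
    args <- ph[setdiff(names(ph), "targets")]
    do.call(phantom_config, c(args, list(targets = targets)))
  }
  mo <- raw$motion
  motion <- if (is.null(mo)) motion_pattern("static")
  else do.call(motion_pattern, mo)
  pr <- raw$protocol
  protocol <- if (is.null(pr)) {
    default_protocol("full_fan", desk_scale = TRUE)
  } else {
    mode <- if (is.null(pr$mode)) "full_fan" else pr$mode
    desk <- isTRUE(pr$desk_scale) || is.null(pr$desk_scale)
    base <- default_protocol(mode, desk_scale = desk)
    for (f in setdiff(names(pr), c("mode", "desk_scale"))) base[[f]] <- pr[[f]]
    do.call(scan_protocol, base[setdiff(names(base), character())])
  }
  list(phantom = phantom, motion = motion, protocol = protocol)
}

#' Write the default configuration to a YAML file
#'
#' Emits a fully populated configuration matching the package defaults, as
#' a starting point for edits.
#'
#' @param path output YAML path.
#' @param config a [phantom_config()].
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path, config = default_phantom_config()) {
  lst <- list(
    phantom = list(
      grid = as.integer(config$grid), spacing = config$spacing[1],
      mu_foam = config$mu_foam, mu_slab = config$mu_slab,
      mu_air = config$mu_air, slab_halfwidth = config$slab_halfwidth,
      foam_halfheight = config$foam_halfheight,
      targets = lapply(config$targets, function(t)
        list(name = t$name, extents = t$extents, center = t$center,
             mu = t$mu))),
    motion = list(kind = "sinusoidal", A = 10, f = 0.25, phi = 0),
    protocol = list(mode = "full_fan", desk_scale = TRUE))
  yaml::write_yaml(lst, path)
  invisible(path)
}
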