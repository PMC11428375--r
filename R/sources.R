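# Source geometry definitions and initial-ray sampling for the sixteen
# optical source types. A source spec is a launch-plane geometry plus a rule
# for drawing (position, direction, weight); pattern sources (Fourier
# families) modulate the initial statistical weight instead of rejecting
# photons, which keeps variance low under the deposit tally.

#' The sixteen source kinds in their canonical order
#'
#' The order (pencil, isotropic, cone, arcsine, line, slit, collimated
#' Gaussian, angular Gaussian, hyperboloid Gaussian, planar, disk, ring,
#' pencil array, spatial-frequency Fourier, 1D Fourier, 2D Fourier) is the
#' fixed 1--16 numbering used for residual tie-breaking in
#' [rank_sources()].
#'
#' @return character vector of length 16.
#' @export
source_kinds <- function() {
  c("pencil", "isotropic", "cone", "arcsine", "line", "slit",
    "collimated_gaussian", "angular_gaussian", "hyperboloid_gaussian",
    "planar", "disk", "ring", "pencil_array",
    "fourier_spatial", "fourier_1d", "fourier_2d")
}

# parameters each kind must carry
.source_required <- list(
  pencil = character(), isotropic = character(),
  cone = "half_angle", arcsine = character(),
  line = "edge1", slit = "edge1",
  collimated_gaussian = "waist",
  angular_gaussian = "zenith_variance",
  hyperboloid_gaussian = c("waist", "focus_distance"),
  planar = c("edge1", "edge2"),
  disk = "outer_radius",
  ring = c("inner_radius", "outer_radius"),
  pencil_array = c("edge1", "edge2", "n1", "n2"),
  fourier_spatial = c("edge1", "edge2", "f1", "f2"),
  fourier_1d = c("edge1", "edge2", "f1"),
  fourier_2d = c("edge1", "edge2", "f1", "f2")
)

#' Define an optical source
#'
#' @param kind one of [source_kinds()].
#' @param origin launch-plane anchor position, mm. For patch sources
#'   (planar, pencil array, Fourier family) this is the patch corner; for
#'   line and slit the segment start; otherwise the beam center.
#' @param axis beam axis; normalized internally.
#' @param ... kind-specific parameters: `half_angle` (rad), `waist` (mm,
#'   1/e^2 intensity radius), `zenith_variance` (rad^2), `focus_distance`
#'   (mm), `edge1`/`edge2` (mm edge vectors), `inner_radius`/`outer_radius`
#'   (mm), `n1`/`n2` (array counts), `f1`/`f2` (cycles per patch), `phase`
#'   (rad, default 0), `modulation` (in [0,1], default 1).
#' @return An object of class `source_spec`.
#' @export
#' @examples
#' source_spec("pencil")
#' source_spec("collimated_gaussian", waist = 1)
#' source_spec("disk", outer_radius = 5)
source_spec <- function(kind, origin = c(7, 7, 0), axis = c(0, 0, 1), ...) {
  kinds <- source_kinds()
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% kinds)) {
    stop("unknown source kind '", paste(kind, collapse = ","),
         "'; valid kinds: ", paste(kinds, collapse = ", "))
  }
  params <- list(...)
  missing <- setdiff(.source_required[[kind]], names(params))
  if (length(missing)) {
    stop("source kind '", kind, "' is missing parameter(s): ",
         paste(missing, collapse = ", "))
  }
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (length(axis) != 3 || nrm == 0) stop("axis must be a nonzero 3-vector")
  axis <- axis / nrm
  for (len_par in c("waist", "outer_radius", "inner_radius", "half_angle",
                    "zenith_variance", "focus_distance")) {
    if (!is.null(params[[len_par]]) && params[[len_par]] < 0) {
      stop(len_par, " must be >= 0")
    }
  }
  if (!is.null(params$modulation) &&
      (params$modulation < 0 || params$modulation > 1)) {
    stop("modulation depth must lie in [0, 1]")
  }
  if (!is.null(params$inner_radius) && !is.null(params$outer_radius) &&
      params$inner_radius > params$outer_radius) {
    stop("inner_radius must not exceed outer_radius")
  }
  if (kind %in% c("fourier_spatial", "fourier_1d", "fourier_2d")) {
    if (is.null(params$phase)) params$phase <- 0
    if (is.null(params$modulation)) params$modulation <- 1
  }
  structure(c(list(kind = kind, origin = as.numeric(origin), axis = axis),
              params),
            class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  extra <- setdiff(names(unclass(x)), c("kind", "origin", "axis"))
  cat(sprintf("<source '%s'> origin (%g, %g, %g) mm, axis (%g, %g, %g)\n",
              x$kind, x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3]))
  for (p in extra) {
    cat(sprintf("  %s: %s\n", p, paste(format(x[[p]]), collapse = " ")))
  }
  invisible(x)
}

#' Load the packaged (or a user) set of source definitions
#'
#' Reads the versioned YAML holding the frozen default parameters for all
#' sixteen source types used by the study sweep.
#'
#' @param file YAML path; default the packaged file.
#' @return Named list of [source_spec()] objects in canonical order.
#' @export
default_sources <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "source_defaults.yaml",
                        package = "voxmc", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(file)
  origin0 <- as.numeric(cfg$origin_mm)
  axis0 <- as.numeric(cfg$axis)
  out <- lapply(names(cfg$sources), function(kind) {
    params <- cfg$sources[[kind]]
    if (is.null(params)) params <- list()
    origin <- if (!is.null(params$origin)) as.numeric(params$origin) else origin0
    params$origin <- NULL
    for (p in c("edge1", "edge2")) {
      if (!is.null(params[[p]])) params[[p]] <- as.numeric(params[[p]])
    }
    do.call(source_spec, c(list(kind = kind, origin = origin, axis = axis0),
                           params))
  })
  setNames(out, names(cfg$sources))
}

# translate a source_spec (or fixed launch) into the flat list the C++
# engine parses; kind_id is the 0-based index into the canonical order
as_engine_source <- function(spec) {
  if (inherits(spec, "photon_launch")) {
    return(list(kind_id = -1L, position = spec$position,
                direction = spec$direction, weight = spec$weight))
  }
  stopifnot(inherits(spec, "source_spec"))
  out <- unclass(spec)
  out$kind_id <- match(spec$kind, source_kinds()) - 1L
  out
}

#' A fixed initial photon ray
#'
#' @param position launch position, mm.
#' @param direction propagation direction; normalized internally.
#' @param weight initial statistical weight in [0, 1].
#' @return An object of class `photon_launch`.
#' @export
photon_launch <- function(position, direction, weight = 1) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero")
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  structure(list(position = as.numeric(position),
                 direction = direction / nrm, weight = weight),
            class = "photon_launch")
}

#' Sample initial photon rays from a source
#'
#' Draws `n` launches (position, unit direction, initial weight) from the
#' source's sampling rule. When a `volume` is given, launches falling
#' outside its entry face are resampled (clipped) with a warning.
#'
#' @param spec a [source_spec()].
#' @param n number of rays.
#' @param seed RNG seed for the self-contained sampling stream.
#' @param volume optional [make_volume()] result used to clip the patch.
#' @return List with `position` and `direction` (n x 3 matrices) and
#'   `weight` (length-n vector).
#' @export
sample_launch <- function(spec, n = 1, seed = 1, volume = NULL) {
  extent <- if (is.null(volume)) numeric(0) else volume$extent
  res <- cpp_sample_launch(as_engine_source(spec), as.integer(n),
                           as.double(seed), extent)
  if (res$clipped > 0) {
    warning(sprintf("source '%s': %d launch(es) fell outside the volume face and were resampled",
                    spec$kind, as.integer(res$clipped)))
  }
  res[c("position", "direction", "weight")]
}
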