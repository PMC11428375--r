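# Analytic test volumes with closed-form depth and FWHM answers, and a
# reduced simulation configuration that runs in seconds. These are smooth
# fields evaluated at voxel centers; they carry no Monte Carlo noise, so
# analysis operators can be checked against exact expectations.

#' Analytic energy volume with known metric answers
#'
#' Evaluates a closed-form field at voxel centers and wraps it as a
#' `fluence_volume` so the whole analysis path accepts it:
#' \describe{
#'   \item{axial_exponential}{`A exp(-z/tau)` times a lateral Gaussian of
#'     width `sigma` centered on the axial column, so the depth at level L
#'     is `tau log(100/L)` before grid snapping.}
#'   \item{lateral_gaussian}{`A exp(-r^2 / (2 sigma^2))`, constant in z;
#'     FWHM `2 sqrt(2 log 2) sigma` at every depth.}
#'   \item{widening_gaussian}{lateral Gaussian whose width grows linearly,
#'     `sigma(z) = sigma + slope z`; FWHM increases monotonically with
#'     depth.}
#'   \item{constant}{uniform field (degenerate for normalization).}
#'   \item{delta}{a single bright voxel on the axis at the entry layer.}
#' }
#' The field center sits on the voxel-center of the column containing
#' x = y = 7 mm (scaled for other shapes), matching the half-open lookup
#' convention of [axial_profile()].
#'
#' @param kind fixture name (see above).
#' @param shape voxel counts, default `c(140,140,140)`.
#' @param voxel_size voxel edge, mm.
#' @param tau axial 1/e decay length, mm.
#' @param sigma lateral Gaussian sd, mm.
#' @param slope widening rate (mm of sd per mm of depth).
#' @param amplitude peak value; default 100 so the field is already on the
#'   normalized scale.
#' @return A `fluence_volume` whose `meta$analytic` records the
#'   generating parameters.
#' @export
#' @examples
#' fv <- analytic_volume("lateral_gaussian", shape = c(60, 60, 10), sigma = 1.5)
#' fwhm(lateral_profile(normalize_energy(fv), "x", depth_mm = 0.5))$width
analytic_volume <- function(kind = c("axial_exponential", "lateral_gaussian",
                                     "widening_gaussian", "constant", "delta"),
                            shape = c(140L, 140L, 140L), voxel_size = 0.1,
                            tau = 2, sigma = 1, slope = 0.5,
                            amplitude = 100) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  stopifnot(all(shape >= 1), voxel_size > 0, tau > 0, sigma > 0,
            amplitude > 0, slope >= 0)
  # axis column: voxel holding the lateral midpoint (70,70 on the default grid)
  icx <- shape[1] %/% 2L
  icy <- shape[2] %/% 2L
  cx <- (icx + 0.5) * voxel_size
  cy <- (icy + 0.5) * voxel_size
  xc <- (seq_len(shape[1]) - 0.5) * voxel_size
  yc <- (seq_len(shape[2]) - 0.5) * voxel_size
  zc <- (seq_len(shape[3]) - 0.5) * voxel_size
  r2 <- outer((xc - cx)^2, (yc - cy)^2, `+`)

  grid <- switch(kind,
    axial_exponential = {
      lat <- exp(-r2 / (2 * sigma^2))
      ax <- amplitude * exp(-zc / tau)
      outer(lat, ax, `*`)
    },
    lateral_gaussian = {
      lat <- amplitude * exp(-r2 / (2 * sigma^2))
      array(rep(lat, shape[3]), dim = shape)
    },
    widening_gaussian = {
      g <- vapply(zc, function(z) exp(-r2 / (2 * (sigma + slope * z)^2)),
                  matrix(0, shape[1], shape[2]))
      array(amplitude * g, dim = shape)
    },
    constant = array(amplitude, dim = shape),
    delta = {
      g <- array(0, dim = shape)
      g[icx + 1L, icy + 1L, 1L] <- amplitude
      g
    })
  dim(grid) <- shape
  structure(list(grid = grid, voxel_size = voxel_size, shape = shape,
                 tallies = list(launched = 1, absorbed = 1, escaped = 0,
                                expired = 0, roulette_boost = 0, clipped = 0),
                 meta = list(analytic = list(kind = kind, tau = tau,
                                             sigma = sigma, slope = slope,
                                             amplitude = amplitude),
                             tissue = list(name = paste0("analytic:", kind),
                                           mu_a = NA_real_),
                             source = list(kind = paste0("analytic:", kind)))),
            class = "fluence_volume")
}

#' Reduced simulation configuration for fast checks
#'
#' A pure function returning a small study setup: a 40^3 cube of 0.1 mm
#' voxels (4 mm edge) and 1e5 photons with a fixed seed, which runs in
#' seconds. Sources should be centered on its entry face at (2, 2, 0) mm.
#'
#' @param tissue tissue label passed to [builtin_tissue()].
#' @param n_photons photon count; default 1e5.
#' @param seed RNG seed; default 42.
#' @return List with `volume`, `config`, and `origin` (the face center).
#' @export
ci_config <- function(tissue = "scalp", n_photons = 1e5, seed = 42L) {
  list(volume = make_volume(builtin_tissue(tissue), shape = c(40L, 40L, 40L),
                            voxel_size = 0.1),
       config = sim_config(n_photons = n_photons, seed = seed),
       origin = c(2, 2, 0))
}
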