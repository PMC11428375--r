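# Monte Carlo transport: R front-end over the compiled engine. The walk is
# the standard voxel scheme: exponential free paths at rate mu_t, continuous
# absorption along every traversed sub-voxel segment (track-length
# estimator), Henyey-Greenstein deflection at interior collision points
# (accepted with probability mu_s/mu_t, the complement being a null
# collision), Fresnel reflection or escape at the cube faces, and unbiased
# Russian roulette below a weight threshold.

#' Run a seeded Monte Carlo simulation
#'
#' Launches `config$n_photons` rays from `source` into `volume` and tallies
#' time-integrated fluence per voxel. The grid is normalized by (voxel
#' volume x launched weight), giving fluence per unit launched weight in
#' 1/mm^2. A fixed seed reproduces the run bit-exactly.
#'
#' @param volume a [make_volume()] result.
#' @param source a [source_spec()].
#' @param config a [sim_config()].
#' @return An object of class `fluence_volume`: `grid` (3D array),
#'   `tallies` (launched / absorbed / escaped / expired weight plus the
#'   roulette reweighting credit), `voxel_size`, and provenance `meta`.
#' @export
#' @examples
#' vol <- make_volume(builtin_tissue("scalp"), shape = c(40, 40, 40))
#' cfg <- sim_config(n_photons = 1e4, seed = 7)
#' fv <- run_simulation(vol, source_spec("pencil", origin = c(2, 2, 0)), cfg)
#' conservation_residual(fv)
run_simulation <- function(volume, source, config = sim_config()) {
  stopifnot(inherits(volume, "sim_volume"), inherits(config, "sim_config"))
  t0 <- Sys.time()
  res <- cpp_run_simulation(
    shape = volume$shape, voxel_size = volume$voxel_size,
    mua = volume$tissue$mu_a, mus = volume$tissue$mu_s,
    g = volume$tissue$g, n_tissue = volume$tissue$n,
    ambient_n = volume$ambient_n,
    source = as_engine_source(source),
    n_photons = config$n_photons, end_time = config$end_time,
    roulette_threshold = config$roulette_threshold,
    roulette_survival = config$roulette_survival,
    reflect_at_boundary = config$reflect_at_boundary,
    seed = config$seed)
  voxvol <- volume$voxel_size^3
  grid <- res$fluence_raw / (voxvol * res$launched)
  tallies <- res[c("launched", "absorbed", "escaped", "expired",
                   "roulette_boost", "clipped")]
  structure(list(
    grid = grid, voxel_size = volume$voxel_size, shape = volume$shape,
    tallies = tallies,
    meta = list(tissue = volume$tissue,
                source = if (inherits(source, "source_spec")) unclass(source) else source,
                config = unclass(config),
                ambient_n = volume$ambient_n,
                n_photons = res$n_photons, seed = config$seed,
                elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                package_version = as.character(utils::packageVersion("voxmc")))),
    class = "fluence_volume")
}

#' @export
print.fluence_volume <- function(x, ...) {
  cat(sprintf("<fluence_volume> %dx%dx%d @ %g mm, tissue '%s', source '%s'\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size,
              x$meta$tissue$name, x$meta$source$kind))
  cat(sprintf("  photons %g, launched weight %g, conservation residual %.2e\n",
              x$meta$n_photons, x$tallies$launched, conservation_residual(x)))
  invisible(x)
}

#' Propagate a single fixed photon
#'
#' Traces one ray given explicitly (rather than drawn from a source) through
#' the volume; useful for auditing the walk against closed forms.
#'
#' @param volume a [make_volume()] result.
#' @param launch a [photon_launch()].
#' @param config a [sim_config()]; `n_photons` is ignored (one photon).
#' @return A `fluence_volume` for the single trace (grid left unnormalized
#'   by photon count beyond the launch weight).
#' @export
propagate_photon <- function(volume, launch, config = sim_config()) {
  stopifnot(inherits(launch, "photon_launch"))
  res <- cpp_run_simulation(
    shape = volume$shape, voxel_size = volume$voxel_size,
    mua = volume$tissue$mu_a, mus = volume$tissue$mu_s,
    g = volume$tissue$g, n_tissue = volume$tissue$n,
    ambient_n = volume$ambient_n,
    source = as_engine_source(launch),
    n_photons = 1, end_time = config$end_time,
    roulette_threshold = config$roulette_threshold,
    roulette_survival = config$roulette_survival,
    reflect_at_boundary = config$reflect_at_boundary,
    seed = config$seed)
  voxvol <- volume$voxel_size^3
  grid <- res$fluence_raw / (voxvol * max(res$launched, .Machine$double.eps))
  structure(list(grid = grid, voxel_size = volume$voxel_size,
                 shape = volume$shape,
                 tallies = res[c("launched", "absorbed", "escaped",
                                 "expired", "roulette_boost", "clipped")],
                 meta = list(tissue = volume$tissue, source = unclass(launch),
                             config = unclass(config),
                             n_photons = 1, seed = config$seed)),
            class = "fluence_volume")
}

#' Relative energy-conservation residual of a run
#'
#' Launched weight plus the roulette reweighting credit must equal absorbed
#' + escaped + expired weight; the residual is the relative imbalance.
#'
#' @param fv a `fluence_volume`.
#' @return Nonnegative number; of order 1e-12 for a correct run.
#' @export
conservation_residual <- function(fv) {
  tl <- fv$tallies
  inflow <- tl$launched + tl$roulette_boost
  outflow <- tl$absorbed + tl$escaped + tl$expired
  abs(inflow - outflow) / max(inflow, .Machine$double.eps)
}

#' Sample exponential free-path lengths
#'
#' @param n number of draws.
#' @param mu_t total attenuation coefficient, 1/mm (> 0).
#' @param seed RNG seed.
#' @return Lengths in mm, distributed Exp(mu_t): `-log(xi)/mu_t`.
#' @export
sample_step <- function(n, mu_t, seed = 1) {
  if (!is.numeric(mu_t) || mu_t <= 0) stop("mu_t must be positive")
  cpp_sample_step(as.integer(n), mu_t, as.double(seed))
}

#' Henyey-Greenstein scattering of a direction
#'
#' Draws `n` scattered unit vectors from an incident direction: deflection
#' cosine sampled from the Henyey-Greenstein distribution with anisotropy
#' `g` (uniform on [-1,1] for g = 0), azimuth uniform.
#'
#' @param direction incident unit vector.
#' @param g anisotropy factor in [-1, 1]; the mean deflection cosine.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return n x 3 matrix of unit vectors.
#' @export
scatter_direction <- function(direction, g, n = 1, seed = 1) {
  if (abs(g) > 1) stop("g must lie in [-1, 1]")
  cpp_scatter_direction(as.numeric(direction), g, as.integer(n),
                        as.double(seed))
}

#' Deposit a straight track into a fluence grid
#'
#' Splits the segment at voxel boundaries (3D DDA) and, for each sub-segment
#' of length l entered with weight w, adds `w (1 - exp(-mu_a l)) / mu_a` to
#' that voxel (the limit `w l` as mu_a -> 0) while attenuating the weight by
#' `exp(-mu_a l)`.
#'
#' @param grid 3D numeric array of raw track-length tallies.
#' @param voxel_size voxel edge, mm.
#' @param start,end segment endpoints, mm; must lie inside the grid.
#' @param weight_in entering weight.
#' @param mu_a absorption coefficient, 1/mm.
#' @return List with the updated `grid`, `weight_out`, and the `absorbed`
#'   increment (`weight_in - weight_out` by construction).
#' @export
deposit_track <- function(grid, voxel_size, start, end, weight_in, mu_a) {
  shape <- dim(grid)
  if (is.null(shape) || length(shape) != 3) stop("grid must be a 3D array")
  extent <- shape * voxel_size
  for (p in list(start, end)) {
    if (any(p < -1e-9) || any(p > extent + 1e-9)) {
      stop("segment endpoint outside the volume")
    }
  }
  cpp_deposit_track(as.numeric(grid), as.integer(shape), voxel_size,
                    as.numeric(start), as.numeric(end), weight_in, mu_a)
}

#' Unpolarized Fresnel reflectance at a refractive-index step
#'
#' @param cos_i cosine of the incidence angle (0 < cos_i <= 1).
#' @param n1 index on the incident side.
#' @param n2 index on the far side.
#' @return Reflectance in [0, 1]; 1 beyond the critical angle.
#' @export
#' @examples
#' fresnel_reflectance(1, 1.37, 1)  # ((1.37-1)/(1.37+1))^2
fresnel_reflectance <- function(cos_i, n1, n2) {
  vapply(cos_i, cpp_fresnel_reflectance, numeric(1), n1 = n1, n2 = n2)
}

#' Absorption map from a fluence map
#'
#' For a homogeneous absorber the absorbed energy density is `mu_a * F`
#' voxelwise, so normalized absorption and normalized fluence coincide.
#'
#' @param fluence a `fluence_volume` or 3D array.
#' @param mu_a absorption coefficient, 1/mm; defaults to the tissue's value
#'   when `fluence` carries provenance.
#' @return 3D array of absorbed energy density.
#' @export
absorption_volume <- function(fluence, mu_a = NULL) {
  grid <- if (inherits(fluence, "fluence_volume")) fluence$grid else fluence
  if (is.null(mu_a)) {
    if (!inherits(fluence, "fluence_volume")) {
      stop("mu_a must be given for a bare array")
    }
    mu_a <- fluence$meta$tissue$mu_a
  }
  mu_a * grid
}
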