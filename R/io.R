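# Persistence and provenance. Volumes are stored as RDS (bit-exact
# round trip) next to a small JSON manifest that records the scientific
# parameters and their digest, so a sweep can be resumed and a stored
# volume re-identified without loading it.

# canonical digest of the scientific parameters of a run; changes iff any
# parameter that affects the physics changes
.run_digest <- function(volume, source, config) {
  src <- if (inherits(source, "source_spec")) unclass(source) else source
  key <- list(tissue = unclass(volume$tissue), shape = volume$shape,
              voxel_size = volume$voxel_size, ambient_n = volume$ambient_n,
              source = src[order(names(src))],
              n_photons = config$n_photons, seed = config$seed,
              end_time = config$end_time,
              roulette_threshold = config$roulette_threshold,
              roulette_survival = config$roulette_survival,
              reflect_at_boundary = config$reflect_at_boundary,
              estimator = config$estimator)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(key, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run manifest for a simulation cell
#'
#' @param volume,source,config the run definition.
#' @return List with the parameter `digest`, labels, and package version.
#' @export
run_manifest <- function(volume, source, config) {
  list(digest = .run_digest(volume, source, config),
       tissue = volume$tissue$name,
       source = if (inherits(source, "source_spec")) source$kind else "fixed",
       seed = config$seed, n_photons = config$n_photons,
       package_version = as.character(utils::packageVersion("voxmc")),
       created = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' Write a fluence volume with its manifest sidecar
#'
#' @param fv a `fluence_volume`.
#' @param path output path (`.rds`); a `.json` sidecar is written next to it.
#' @param manifest optional manifest list to store in the sidecar.
#' @return `path`, invisibly.
#' @export
write_fluence <- function(fv, path, manifest = NULL) {
  stopifnot(inherits(fv, "fluence_volume"))
  saveRDS(fv, path)
  side <- c(manifest,
            list(tallies = fv$tallies, shape = fv$shape,
                 voxel_size_mm = fv$voxel_size))
  jsonlite::write_json(side, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a stored fluence volume
#'
#' @param path an `.rds` file written by [write_fluence()].
#' @return The `fluence_volume`, bit-identical to what was written.
#' @export
read_fluence <- function(path) {
  fv <- readRDS(path)
  if (!inherits(fv, "fluence_volume")) stop("not a stored fluence volume: ", path)
  fv
}

#' Write tidy sweep metrics to CSV
#'
#' @param metrics data.frame from [sweep_metrics()] or [run_sweep()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
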