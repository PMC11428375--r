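# Quantitative analysis of simulated energy maps: 0-100 normalization,
# axial penetration depth at fixed energy levels, lateral FWHM, and source
# ranking with the study's tie rule.

#' Normalize an energy volume to the 0--100 range
#'
#' Rescales voxelwise as `(E - E_min) / (E_max - E_min) * 100`, with the
#' extrema taken over the whole volume. Because absorption is proportional
#' to fluence in a homogeneous absorber, the same normalized map describes
#' both.
#'
#' @param fluence a `fluence_volume` or a 3D array.
#' @return An object of class `normalized_volume`: `grid` in \[0, 100\],
#'   `e_min`, `e_max`, `voxel_size`, and `provenance`.
#' @export
normalize_energy <- function(fluence) {
  is_fv <- inherits(fluence, "fluence_volume")
  grid <- if (is_fv) fluence$grid else fluence
  if (!all(is.finite(grid))) stop("grid must be finite")
  e_min <- min(grid); e_max <- max(grid)
  if (e_max == e_min) stop("constant field cannot be normalized")
  structure(list(grid = (grid - e_min) / (e_max - e_min) * 100,
                 e_min = e_min, e_max = e_max,
                 voxel_size = if (is_fv) fluence$voxel_size else attr(fluence, "voxel_size"),
                 provenance = if (is_fv) fluence$meta else NULL),
            class = "normalized_volume")
}

#' @export
print.normalized_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<normalized_volume> %dx%dx%d, raw range [%g, %g]\n",
              d[1], d[2], d[3], x$e_min, x$e_max))
  invisible(x)
}

# mm coordinate -> 0-based voxel index under the half-open convention
.voxel_index <- function(coord_mm, voxel_size, n) {
  idx <- floor(coord_mm / voxel_size + 1e-9)
  if (idx < 0 || idx >= n) stop("coordinate ", coord_mm, " mm outside the volume")
  as.integer(idx)
}

.nv_voxel <- function(nv) {
  vs <- nv$voxel_size
  if (is.null(vs)) stop("normalized volume carries no voxel size")
  vs
}

#' Axial energy profile on the source axis
#'
#' Extracts the z-column of normalized energy through the voxel containing
#' (x_mm, y_mm); with the default half-open voxel convention the line
#' x = y = 7 mm maps to voxel column (70, 70) of the 140^3 grid. The
#' `depths` are voxel-center z positions.
#'
#' @param nv a [normalize_energy()] result.
#' @param x_mm,y_mm lateral position of the column, mm.
#' @return An object of class `axial_profile` with `depths` (mm) and
#'   `values` (normalized energy).
#' @export
axial_profile <- function(nv, x_mm = 7, y_mm = 7) {
  stopifnot(inherits(nv, "normalized_volume"))
  vs <- .nv_voxel(nv)
  d <- dim(nv$grid)
  ix <- .voxel_index(x_mm, vs, d[1])
  iy <- .voxel_index(y_mm, vs, d[2])
  structure(list(depths = (seq_len(d[3]) - 0.5) * vs,
                 values = nv$grid[ix + 1L, iy + 1L, ],
                 voxel_size = vs, x_mm = x_mm, y_mm = y_mm),
            class = "axial_profile")
}

#' Deepest axial position reaching an energy level
#'
#' Returns the depth of the deepest voxel whose normalized value is at
#' least `level` (percent of the volume maximum, i.e. the normalized value
#' itself). Depth is reported as `(index + 1) * voxel_size` with 0-based
#' indices, so a column qualifying over its whole length reports the full
#' physical depth (14.0 mm on the default grid). `NA` when no voxel
#' qualifies.
#'
#' @param profile an [axial_profile()], or a numeric vector of normalized
#'   values (then `voxel_size` must be given).
#' @param level threshold in (0, 100].
#' @param voxel_size spacing for a bare numeric profile, mm.
#' @return Depth in mm, or `NA_real_` if the level is never reached.
#' @export
max_depth_at_level <- function(profile, level, voxel_size = NULL) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 100) {
    stop("level must lie in (0, 100]")
  }
  if (inherits(profile, "axial_profile")) {
    values <- profile$values
    voxel_size <- profile$voxel_size
  } else {
    values <- as.numeric(profile)
    if (is.null(voxel_size)) stop("voxel_size needed for a bare profile")
  }
  hit <- which(values >= level)
  if (!length(hit)) return(NA_real_)
  max(hit) * voxel_size
}

#' Lateral energy profile at a depth
#'
#' Extracts normalized energy along X (through the y = y_mm column) or
#' along Y (through the x = x_mm column) in the slice containing
#' `depth_mm` under the half-open convention (12 mm -> 0-based slice 120).
#'
#' @param nv a [normalize_energy()] result.
#' @param axis `"x"` or `"y"`.
#' @param depth_mm slice depth, mm.
#' @param x_mm,y_mm the fixed lateral coordinate of the profile line.
#' @return An object of class `lateral_profile` with `positions` (mm,
#'   voxel centers) and `values`.
#' @export
lateral_profile <- function(nv, axis = c("x", "y"), depth_mm,
                            x_mm = 7, y_mm = 7) {
  stopifnot(inherits(nv, "normalized_volume"))
  axis <- tolower(axis); axis <- match.arg(axis)
  vs <- .nv_voxel(nv)
  d <- dim(nv$grid)
  iz <- .voxel_index(depth_mm, vs, d[3])
  if (axis == "x") {
    iy <- .voxel_index(y_mm, vs, d[2])
    values <- nv$grid[, iy + 1L, iz + 1L]
    npos <- d[1]
  } else {
    ix <- .voxel_index(x_mm, vs, d[1])
    values <- nv$grid[ix + 1L, , iz + 1L]
    npos <- d[2]
  }
  structure(list(positions = (seq_len(npos) - 0.5) * vs, values = values,
                 axis = axis, depth_mm = depth_mm, voxel_size = vs),
            class = "lateral_profile")
}

#' Full width at half maximum of a 1D profile
#'
#' The threshold is the midpoint between the profile minimum and its peak.
#' Walking outward from the peak on each side, the half crossing is
#' linearly interpolated between the last sample at or above the threshold
#' and the first sample below it; the width is the distance between the two
#' crossings. A side that never falls below the threshold is bounded at the
#' profile edge and flagged `censored`.
#'
#' @param profile a [lateral_profile()] or numeric vector.
#' @param sample_spacing spacing in mm for a bare vector.
#' @return List of class `fwhm_result`: `width` (mm), `censored` (logical),
#'   `left`, `right` (crossing positions, mm).
#' @export
#' @examples
#' x <- seq(-5, 5, by = 0.1)
#' fwhm(exp(-x^2 / 2), sample_spacing = 0.1)$width  # ~ 2.3548
fwhm <- function(profile, sample_spacing = NULL) {
  if (inherits(profile, "lateral_profile")) {
    values <- profile$values
    sample_spacing <- profile$voxel_size
  } else {
    values <- as.numeric(profile)
    if (is.null(sample_spacing)) stop("sample_spacing needed for a bare profile")
  }
  n <- length(values)
  if (n < 3) stop("profile needs at least 3 samples")
  p_max <- max(values); p_min <- min(values)
  if (p_max == p_min) stop("all-equal profile has no peak")
  thr <- p_min + (p_max - p_min) / 2
  peak <- which.max(values)
  pos <- (seq_len(n) - 1) * sample_spacing

  cross_one <- function(step) { # step -1 left, +1 right
    i <- peak
    while (TRUE) {
      j <- i + step
      if (j < 1 || j > n) return(list(x = pos[i], censored = TRUE))
      if (values[j] < thr) {
        frac <- (values[i] - thr) / (values[i] - values[j])
        return(list(x = pos[i] + step * frac * sample_spacing,
                    censored = FALSE))
      }
      i <- j
    }
  }
  left <- cross_one(-1L)
  right <- cross_one(+1L)
  structure(list(width = right$x - left$x,
                 censored = left$censored || right$censored,
                 left = left$x, right = right$x, threshold = thr),
            class = "fwhm_result")
}

#' FWHM as a function of depth
#'
#' Applies [fwhm()] to the lateral profile of every depth slice. Slices are
#' labelled by the lower edge of the voxel layer (0-based index x voxel
#' size), matching the half-open slice lookup of [lateral_profile()].
#'
#' @param nv a [normalize_energy()] result.
#' @param axis `"x"` or `"y"`.
#' @param x_mm,y_mm lateral position of the profile line.
#' @return A data.frame with `depth_mm`, `width_mm`, `censored`.
#' @export
fwhm_vs_depth <- function(nv, axis = c("x", "y"), x_mm = 7, y_mm = 7) {
  axis <- match.arg(axis)
  d <- dim(nv$grid)
  vs <- .nv_voxel(nv)
  rows <- lapply(seq_len(d[3]) - 1L, function(iz) {
    lp <- lateral_profile(nv, axis, depth_mm = (iz + 0.5) * vs,
                          x_mm = x_mm, y_mm = y_mm)
    fw <- tryCatch(fwhm(lp), error = function(e) NULL)
    data.frame(depth_mm = iz * vs,
               width_mm = if (is.null(fw)) NA_real_ else fw$width,
               censored = if (is.null(fw)) NA else fw$censored)
  })
  do.call(rbind, rows)
}

#' Rank source types by a metric with the study's tie rule
#'
#' Sorts sources by value (descending for `direction = "max"`, ascending
#' for `"min"`). Ties on the focal value are broken by the number of
#' sibling conditions (other rows of `siblings` sharing a `condition`
#' label) in which the tied source attains the condition's best value;
#' residual ties fall back on the fixed 1--16 source numbering of
#' [source_kinds()].
#'
#' @param values data.frame with columns `source` and `value` (one row per
#'   source), or a named numeric vector.
#' @param k number of sources to return; the full ranking if `k` exceeds
#'   the number of sources.
#' @param direction `"max"` or `"min"`.
#' @param siblings optional data.frame (`source`, `condition`, `value`)
#'   holding the same metric in related conditions, used only for ties.
#' @return data.frame `source`, `value` in rank order (first `k` rows).
#' @export
rank_sources <- function(values, k = 3, direction = c("max", "min"),
                         siblings = NULL) {
  direction <- match.arg(direction)
  if (is.numeric(values) && !is.null(names(values))) {
    values <- data.frame(source = names(values), value = as.numeric(values),
                         stringsAsFactors = FALSE)
  }
  if (!is.data.frame(values) || !all(c("source", "value") %in% names(values))) {
    stop("values must be a data.frame with columns source, value")
  }
  if (!nrow(values)) stop("empty input: nothing to rank")
  if (anyDuplicated(values$source)) stop("one value per source required")
  sgn <- if (direction == "max") -1 else 1

  tie_wins <- rep(0, nrow(values))
  if (!is.null(siblings) && nrow(siblings)) {
    best_by_cond <- tapply(siblings$value, siblings$condition,
                           if (direction == "max") max else min,
                           na.rm = TRUE)
    wins <- function(src) {
      rows <- siblings[siblings$source == src & !is.na(siblings$value), ]
      if (!nrow(rows)) return(0)
      sum(rows$value == best_by_cond[as.character(rows$condition)])
    }
    tie_wins <- vapply(values$source, wins, numeric(1))
  }
  canon <- match(values$source, source_kinds())
  canon[is.na(canon)] <- length(source_kinds()) + seq_len(sum(is.na(canon)))
  ord <- order(sgn * values$value, -tie_wins, canon, na.last = TRUE)
  out <- values[ord, c("source", "value")]
  rownames(out) <- NULL
  utils::head(out, n = min(k, nrow(out)))
}

#' Per-volume depth and FWHM metrics
#'
#' Normalizes a fluence volume and extracts the axial penetration depths at
#' the given levels plus the lateral FWHM along X and Y at `fwhm_depth_mm`.
#'
#' @param fv a `fluence_volume`.
#' @param levels normalized-energy levels, percent of the volume maximum.
#' @param fwhm_depth_mm slice depth for the FWHM metrics, mm.
#' @param x_mm,y_mm lateral position of the axis column; defaults to the
#'   central voxel column of the grid.
#' @return data.frame in tidy form: `metric` ("depth" or "fwhm"), `axis`,
#'   `level`, `depth_mm`, `width_mm`, `censored`.
#' @export
volume_metrics <- function(fv, levels = c(1, 0.1, 0.01), fwhm_depth_mm = 12,
                           x_mm = NULL, y_mm = NULL) {
  nv <- normalize_energy(fv)
  d <- dim(nv$grid)
  # default to the central axis column; (7.05, 7.05) mm on the default grid,
  # i.e. the same (70, 70) voxel column as the study's x = y = 7 mm line
  if (is.null(x_mm)) x_mm <- (d[1] %/% 2 + 0.5) * nv$voxel_size
  if (is.null(y_mm)) y_mm <- (d[2] %/% 2 + 0.5) * nv$voxel_size
  ap <- axial_profile(nv, x_mm = x_mm, y_mm = y_mm)
  depth_rows <- data.frame(
    metric = "depth", axis = NA_character_, level = levels,
    depth_mm = vapply(levels, function(L) max_depth_at_level(ap, L), numeric(1)),
    width_mm = NA_real_, censored = NA)
  fwhm_rows <- do.call(rbind, lapply(c("x", "y"), function(ax) {
    fw <- fwhm(lateral_profile(nv, ax, depth_mm = fwhm_depth_mm,
                               x_mm = x_mm, y_mm = y_mm))
    data.frame(metric = "fwhm", axis = ax, level = NA_real_,
               depth_mm = fwhm_depth_mm, width_mm = fw$width,
               censored = fw$censored)
  }))
  rbind(depth_rows, fwhm_rows)
}

#' Assemble study-style summary tables from a full sweep
#'
#' From tidy sweep metrics (one row per tissue x source x metric cell)
#' builds the two headline tables: per tissue and energy level the top-k
#' sources by penetration depth, and per tissue and lateral axis the top-k
#' and bottom-k sources by FWHM at the reference depth. Values are rounded
#' to 0.1 mm in the report columns; raw values are retained.
#'
#' @param metrics data.frame as returned by [sweep_metrics()] /
#'   [volume_metrics()] with a `tissue` and `source` column.
#' @param k how many sources to keep per cell.
#' @return List with data.frames `depth` and `fwhm`.
#' @export
make_tables <- function(metrics, k = 3) {
  need <- c("tissue", "source", "metric", "axis", "level",
            "depth_mm", "width_mm")
  if (!all(need %in% names(metrics))) {
    stop("metrics must have columns: ", paste(need, collapse = ", "))
  }
  dep <- metrics[metrics$metric == "depth", ]
  fwh <- metrics[metrics$metric == "fwhm", ]
  tissues <- unique(metrics$tissue)
  sources <- unique(metrics$source)
  levels <- sort(unique(dep$level), decreasing = TRUE)

  full <- expand.grid(tissue = tissues, source = sources, level = levels,
                      stringsAsFactors = FALSE)
  have <- paste(dep$tissue, dep$source, dep$level)
  miss <- full[!(paste(full$tissue, full$source, full$level) %in% have), ]
  if (nrow(miss)) {
    stop("incomplete sweep; missing depth cells: ",
         paste(utils::head(paste(miss$tissue, miss$source, miss$level), 10),
               collapse = "; "))
  }

  depth_tab <- do.call(rbind, lapply(tissues, function(ti) {
    do.call(rbind, lapply(levels, function(L) {
      cell <- dep[dep$tissue == ti & dep$level == L, ]
      sib <- dep[dep$tissue == ti & dep$level != L, ]
      top <- rank_sources(
        data.frame(source = cell$source, value = cell$depth_mm), k = k,
        direction = "max",
        siblings = data.frame(source = sib$source, condition = sib$level,
                              value = sib$depth_mm))
      data.frame(tissue = ti, level = L, rank = seq_len(nrow(top)),
                 source = top$source, depth_mm = round(top$value, 1),
                 depth_mm_raw = top$value)
    }))
  }))

  fwhm_tab <- do.call(rbind, lapply(tissues, function(ti) {
    do.call(rbind, lapply(unique(fwh$axis), function(ax) {
      cell <- fwh[fwh$tissue == ti & fwh$axis == ax, ]
      sib <- fwh[fwh$tissue == ti & fwh$axis != ax, ]
      sib_df <- data.frame(source = sib$source, condition = sib$axis,
                           value = sib$width_mm)
      do.call(rbind, lapply(c("max", "min"), function(dir) {
        top <- rank_sources(
          data.frame(source = cell$source, value = cell$width_mm), k = k,
          direction = dir, siblings = sib_df)
        data.frame(tissue = ti, axis = ax, extreme = dir,
                   rank = seq_len(nrow(top)), source = top$source,
                   width_mm = round(top$value, 1), width_mm_raw = top$value)
      }))
    }))
  }))
  list(depth = depth_tab, fwhm = fwhm_tab)
}
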