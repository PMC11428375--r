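nv_from_grid <- function(grid, voxel_size = 0.1) {
  structure(list(grid = grid, e_min = min(grid), e_max = max(grid),
                 voxel_size = voxel_size), class = "normalized_volume")
}

test_that("normalization maps extrema to 0 and 100 and is idempotent", {
  g <- array(runif(8 * 8 * 8, 0, 5), dim = c(8, 8, 8))
  g[1] <- 0; g[2] <- 5
  nv <- normalize_energy(g)
  expect_equal(min(nv$grid), 0)
  expect_equal(max(nv$grid), 100)
  expect_equal(nv$grid, g * 20, tolerance = 1e-12)
  # idempotent: renormalizing changes nothing
  nv2 <- normalize_energy(nv$grid)
  expect_equal(nv2$grid, nv$grid, tolerance = 1e-12)
  expect_error(normalize_energy(array(3, dim = c(4, 4, 4))), "constant")
  expect_error(normalize_energy(array(c(1, NA, 2, 3), dim = c(2, 2, 1))),
               "finite")
})

test_that("axial profile extracts the half-open voxel column at x = y = 7 mm", {
  g <- array(0, dim = c(140, 140, 140))
  colvals <- seq(100, 0.1, length.out = 140)
  g[71, 71, ] <- colvals # 0-based voxel (70, 70): contains 7 mm
  ap <- axial_profile(nv_from_grid(g), 7, 7)
  expect_equal(ap$values, colvals)
  expect_equal(ap$depths, (1:140 - 0.5) * 0.1)
  expect_error(axial_profile(nv_from_grid(g), 15, 7), "outside")
})

test_that("depth-at-level matches the exponential closed form after grid snap", {
  tau <- 2
  f <- function(z) 100 * exp(-z / tau)
  profile <- f((0:139 + 0.5) * 0.1)
  for (L in c(1, 0.1)) {
    got <- max_depth_at_level(profile, L, voxel_size = 0.1)
    expect_equal(got, oracle_depth(f, L, 140, 0.1))
    # within half a voxel of the continuous answer tau*log(100/L)
    expect_lt(abs(got - tau * log(100 / L)), 0.05 + 1e-9)
  }
  # saturated column reports the full depth
  expect_equal(max_depth_at_level(rep(100, 140), 1, voxel_size = 0.1), 14)
  # absent when the level is never reached
  expect_true(is.na(max_depth_at_level(profile * 0.005, 1, voxel_size = 0.1)))
  expect_error(max_depth_at_level(profile, 0, voxel_size = 0.1), "level")
  expect_error(max_depth_at_level(profile, 101, voxel_size = 0.1), "level")
})

test_that("depth is monotone in the level: 1% <= 0.1% <= 0.01%", {
  set.seed(71)
  for (i in 1:20) {
    prof <- rev(sort(runif(140, 0, 100)))
    d <- vapply(c(1, 0.1, 0.01), function(L)
      max_depth_at_level(prof, L, voxel_size = 0.1), numeric(1))
    d[is.na(d)] <- 0
    expect_true(d[1] <= d[2] && d[2] <= d[3])
  }
})

test_that("lateral profile follows the half-open slice convention", {
  g <- array(0, dim = c(140, 140, 140))
  g[, 71, 121] <- 1:140 # slice covering [12.0, 12.1) mm
  lp <- lateral_profile(nv_from_grid(g), "x", depth_mm = 12)
  expect_equal(lp$values, 1:140)
  lpy <- lateral_profile(nv_from_grid(g), "y", depth_mm = 12)
  expect_equal(lpy$values, g[71, , 121])
  expect_error(lateral_profile(nv_from_grid(g), "x", depth_mm = 14.5),
               "outside")
})

test_that("FWHM matches Gaussian and triangle closed forms", {
  # Gaussian, sigma = 1 mm on a fine grid with zero baseline
  x <- seq(0, 20, by = 0.05)
  prof <- exp(-(x - 10)^2 / 2)
  fw <- fwhm(prof, sample_spacing = 0.05)
  expect_lt(abs(fw$width - 2 * sqrt(2 * log(2))), 0.025 + 1e-9)
  expect_false(fw$censored)
  # triangle with base half-width h: FWHM is exactly h under linear interp
  h <- 2.4
  xt <- seq(-5, 5, by = 0.1)
  tri <- pmax(0, 1 - abs(xt) / h)
  expect_equal(fwhm(tri, sample_spacing = 0.1)$width, h, tolerance = 1e-9)
  # single nonzero sample: crossings sit in the two neighboring gaps
  single <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(fwhm(single, sample_spacing = 0.1)$width, 0.1, tolerance = 1e-12)
  expect_error(fwhm(rep(2, 10), sample_spacing = 0.1), "no peak")
})

test_that("FWHM is invariant under positive affine transforms and flags censoring", {
  x <- seq(0, 14, by = 0.1)
  prof <- 40 * exp(-(x - 7)^2 / (2 * 1.5^2)) + 3
  w0 <- fwhm(prof, sample_spacing = 0.1)$width
  for (ab in list(c(2, 0), c(0.5, 10), c(7, 3))) {
    w <- fwhm(ab[1] * prof + ab[2], sample_spacing = 0.1)$width
    expect_equal(w, w0, tolerance = 1e-12)
  }
  # a profile that rises to a plateau never falls to half on the right
  plateau <- c(seq(0, 1, by = 0.1), rep(0.95, 20))
  fw <- fwhm(plateau, sample_spacing = 0.1)
  expect_true(fw$censored)
  expect_equal(fw$right, (length(plateau) - 1) * 0.1)
})

test_that("FWHM agrees with an independent fine-grid oracle on fixtures", {
  sigma <- 1.5
  fv <- analytic_volume("lateral_gaussian", shape = c(140, 140, 20),
                        sigma = sigma)
  nv <- normalize_energy(fv)
  got <- fwhm(lateral_profile(nv, "x", depth_mm = 1))$width
  want <- oracle_fwhm(function(x) exp(-(x - 7.05)^2 / (2 * sigma^2)), 0, 14)
  expect_lt(abs(got - want), 0.05 + 1e-9)
  expect_lt(abs(want - 2 * sqrt(2 * log(2)) * sigma), 1e-3)
  # X and Y profiles of the axisymmetric fixture agree
  goty <- fwhm(lateral_profile(nv, "y", depth_mm = 1))$width
  expect_equal(got, goty, tolerance = 1e-12)
})

test_that("FWHM-versus-depth is monotone for a widening beam and flat for a constant one", {
  fv <- analytic_volume("widening_gaussian", shape = c(100, 100, 30),
                        sigma = 0.8, slope = 0.5)
  series <- fwhm_vs_depth(normalize_energy(fv), "x", x_mm = 5, y_mm = 5)
  expect_equal(series$depth_mm, (0:29) * 0.1)
  expect_true(all(diff(series$width_mm) > 0))
  fv2 <- analytic_volume("lateral_gaussian", shape = c(100, 100, 30),
                         sigma = 1.2)
  series2 <- fwhm_vs_depth(normalize_energy(fv2), "y", x_mm = 5, y_mm = 5)
  expect_lt(diff(range(series2$width_mm)), 1e-9)
})

test_that("source ranking sorts, breaks ties by sibling wins, then canon order", {
  vals <- data.frame(source = c("A", "B", "C"), value = c(5, 7, 6))
  expect_equal(rank_sources(vals, k = 3)$source, c("B", "C", "A"))
  expect_equal(rank_sources(vals, k = 2, direction = "min")$source, c("A", "C"))
  # k beyond the input returns the full ranking
  expect_equal(nrow(rank_sources(vals, k = 10)), 3L)
  # tie: the source that wins more sibling conditions goes first
  vals2 <- data.frame(source = c("planar", "disk", "pencil"),
                      value = c(9, 9, 3))
  sib <- data.frame(source = rep(c("planar", "disk", "pencil"), 2),
                    condition = rep(c("l1", "l2"), each = 3),
                    value = c(5, 6, 1, 4, 6, 2))
  expect_equal(rank_sources(vals2, k = 3, siblings = sib)$source[1], "disk")
  # residual tie falls back on the fixed 1-16 source order
  vals3 <- data.frame(source = c("disk", "planar"), value = c(2, 2))
  expect_equal(rank_sources(vals3, k = 2)$source, c("planar", "disk"))
  expect_error(rank_sources(vals[0, ]), "empty")
  expect_error(rank_sources(data.frame(source = c("A", "A"), value = 1:2)),
               "one value per source")
})

test_that("ranking output is a permutation, stable under input reordering", {
  set.seed(5)
  vals <- data.frame(source = sample(source_kinds(), 8),
                     value = round(runif(8, 0, 10), 1))
  r1 <- rank_sources(vals, k = 8)
  expect_setequal(r1$source, vals$source)
  r2 <- rank_sources(vals[sample(8), ], k = 8)
  expect_identical(r1, r2)
})

test_that("summary tables report top and bottom sources per condition", {
  tissues <- c("t1", "t2")
  sources <- c("pencil", "planar", "disk")
  grid <- expand.grid(tissue = tissues, source = sources,
                      level = c(1, 0.1, 0.01), stringsAsFactors = FALSE)
  grid$metric <- "depth"; grid$axis <- NA_character_
  grid$depth_mm <- c(seq(3, by = 0.5, length.out = nrow(grid)))
  grid$width_mm <- NA_real_; grid$censored <- NA
  fw <- expand.grid(tissue = tissues, source = sources, axis = c("x", "y"),
                    stringsAsFactors = FALSE)
  fw$metric <- "fwhm"; fw$level <- NA_real_
  fw$depth_mm <- 12; fw$censored <- FALSE
  fw$width_mm <- seq(6, by = 0.25, length.out = nrow(fw))
  tabs <- make_tables(rbind(grid, fw), k = 2)
  expect_setequal(names(tabs), c("depth", "fwhm"))
  # deepest source for t1 at level 1: the largest constructed value wins
  cell <- grid[grid$tissue == "t1" & grid$level == 1, ]
  expect_equal(tabs$depth$source[tabs$depth$tissue == "t1" &
                                 tabs$depth$level == 1][1],
               cell$source[which.max(cell$depth_mm)])
  expect_true(all(tabs$fwhm$extreme %in% c("max", "min")))
  # missing cells are reported, not silently dropped
  expect_error(make_tables(rbind(grid[-1, ], fw)), "missing")
})
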