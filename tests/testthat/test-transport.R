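test_that("free-path lengths are Exp(mu_t) with the exact mean", {
  for (mu_t in c(1, 19.018)) {
    s <- sample_step(2e5, mu_t, seed = 3)
    expect_true(all(s >= 0))
    # mean and sd of Exp(mu_t) are both 1/mu_t; 4 standard errors
    expect_equal(mean(s), 1 / mu_t, tolerance = 4 / sqrt(2e5))
  }
  expect_error(sample_step(10, 0), "positive")
  expect_error(sample_step(10, -1), "positive")
})

test_that("Henyey-Greenstein deflection recovers its first moment g", {
  n <- 2e5
  for (g in c(0, 0.9, 0.99)) {
    d <- scatter_direction(c(0, 0, 1), g, n = n, seed = 41)
    expect_true(all(abs(sqrt(rowSums(d^2)) - 1) < 1e-9))
    ct <- d[, 3] # cos(theta) against the incident +z direction
    expect_lt(abs(mean(ct) - g), 3 * sd(ct) / sqrt(n))
  }
  # incident direction off-axis: moment measured against that direction
  inc <- c(1, 2, -2) / 3
  d <- scatter_direction(inc, 0.9, n = n, seed = 42)
  ct <- d %*% inc
  expect_lt(abs(mean(ct) - 0.9), 3 * sd(ct) / sqrt(n))
})

test_that("track deposit matches the closed-form attenuation and conserves weight", {
  g0 <- array(0, dim = c(10, 10, 10))
  # lossless limit: mu_a = 0 deposits w * l and passes the weight through
  r <- deposit_track(g0, 1, start = c(5.5, 5.5, 2), end = c(5.5, 5.5, 3),
                     weight_in = 1, mu_a = 0)
  expect_equal(sum(r$grid), 1, tolerance = 1e-9)
  expect_equal(r$weight_out, 1)
  # gray-matter coefficient over one 0.1 mm sub-voxel path
  g1 <- array(0, dim = c(40, 40, 40))
  r <- deposit_track(g1, 0.1, start = c(2.05, 2.05, 1), end = c(2.05, 2.05, 1.1),
                     weight_in = 1, mu_a = 0.036)
  expect_equal(r$weight_out, exp(-0.0036), tolerance = 1e-9)
  expect_equal(r$absorbed, 1 - r$weight_out, tolerance = 1e-12)
  # splitting at voxel boundaries preserves the total track length
  r2 <- deposit_track(g1, 0.1, start = c(1.23, 1.91, 0.4),
                      end = c(2.87, 3.05, 3.2), weight_in = 1, mu_a = 0)
  len <- sqrt(sum((c(2.87, 3.05, 3.2) - c(1.23, 1.91, 0.4))^2))
  expect_equal(sum(r2$grid), len, tolerance = 1e-6)
  expect_error(deposit_track(g1, 0.1, c(-1, 0, 0), c(1, 1, 1), 1, 0.1),
               "outside")
})

test_that("Fresnel reflectance matches closed forms and bounds", {
  expect_equal(fresnel_reflectance(1, 1.37, 1), ((1.37 - 1) / (1.37 + 1))^2,
               tolerance = 1e-12)
  # beyond the critical angle: total internal reflection
  cos_crit <- sqrt(1 - (1 / 1.37)^2)
  expect_equal(fresnel_reflectance(cos_crit * 0.9, 1.37, 1), 1)
  # matched media reflect nothing
  expect_equal(fresnel_reflectance(0.7, 1.4, 1.4), 0, tolerance = 1e-12)
  cc <- seq(0.01, 1, by = 0.01)
  r <- fresnel_reflectance(cc, 1.37, 1)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("without scattering a pencil ray stays on its axis column", {
  tis <- test_tissue(mu_a = 0.3, mu_s = 0)
  vol <- make_volume(tis, shape = c(20, 20, 20), voxel_size = 0.1)
  fv <- propagate_photon(vol, photon_launch(c(1.05, 1.05, 0), c(0, 0, 1)),
                         sim_config(n_photons = 1, seed = 5,
                                    reflect_at_boundary = FALSE))
  on_axis <- fv$grid[11, 11, ]
  expect_true(all(on_axis > 0))
  off <- fv$grid; off[11, 11, ] <- 0
  expect_true(all(off == 0))
})

test_that("a zero time gate expires all weight and deposits nothing", {
  cc <- ci_config()
  fv <- run_simulation(cc$volume, source_spec("pencil", origin = cc$origin),
                       sim_config(n_photons = 100, seed = 2,
                                  end_time = 1e-16))
  expect_gt(fv$tallies$expired, 0.999 * fv$tallies$launched)
  expect_lt(conservation_residual(fv), 1e-6)
  expect_lt(sum(fv$grid) * cc$volume$voxel_size^3, 1e-3)
})

test_that("energy is conserved to 1e-6 on seeded runs across tissues and sources", {
  combos <- list(
    list(tissue = "scalp", src = source_spec("pencil", origin = c(2, 2, 0))),
    list(tissue = "cerebrospinal fluid",
         src = source_spec("isotropic", origin = c(2, 2, 0))),
    list(tissue = "blood vessel",
         src = source_spec("collimated_gaussian", origin = c(2, 2, 0),
                           waist = 0.5)),
    list(tissue = "white matter",
         src = source_spec("disk", origin = c(2, 2, 0), outer_radius = 1)))
  for (i in seq_along(combos)) {
    cc <- ci_config(combos[[i]]$tissue, n_photons = 2e4, seed = 100 + i)
    fv <- run_simulation(cc$volume, combos[[i]]$src, cc$config)
    expect_lt(conservation_residual(fv), 1e-6,
              label = combos[[i]]$tissue)
    expect_true(all(fv$grid >= 0))
  }
})

test_that("identical seeds reproduce runs bit-exactly; different seeds differ", {
  cc <- ci_config(n_photons = 5e3)
  src <- source_spec("collimated_gaussian", origin = cc$origin, waist = 1)
  f1 <- run_simulation(cc$volume, src, cc$config)
  f2 <- run_simulation(cc$volume, src, cc$config)
  expect_identical(f1$grid, f2$grid)
  expect_identical(f1$tallies, f2$tallies)
  f3 <- run_simulation(cc$volume, src, sim_config(n_photons = 5e3, seed = 43))
  expect_false(identical(f1$grid, f3$grid))
})

test_that("with scattering off the axial decay recovers Beer-Lambert within 2%", {
  tis <- test_tissue(mu_a = 0.3, mu_s = 0, n = 1.37)
  vol <- make_volume(tis, shape = c(21, 21, 60), voxel_size = 0.1)
  fv <- run_simulation(vol, source_spec("pencil", origin = c(1.05, 1.05, 0)),
                       sim_config(n_photons = 1e4, seed = 8,
                                  reflect_at_boundary = FALSE))
  prof <- fv$grid[11, 11, ]
  z <- (seq_along(prof) - 0.5) * 0.1
  fit <- stats::lm(log(prof) ~ z)
  expect_equal(unname(stats::coef(fit)[2]), -0.3, tolerance = 0.02)
})

test_that("absorption map is mu_a times fluence and shares its normalization", {
  cc <- ci_config("gray matter", n_photons = 2e4, seed = 12)
  fv <- run_simulation(cc$volume, source_spec("pencil", origin = cc$origin),
                       cc$config)
  A <- absorption_volume(fv)
  expect_equal(A, 0.036 * fv$grid)
  expect_equal(absorption_volume(fv$grid, mu_a = 0), 0 * fv$grid)
  # normalized absorption == normalized fluence for a homogeneous absorber
  fvA <- fv; fvA$grid <- A
  expect_equal(normalize_energy(fvA)$grid, normalize_energy(fv)$grid,
               tolerance = 1e-12)
})

test_that("voxel-tally noise shrinks like 1/sqrt(n_photons)", {
  cc <- ci_config(n_photons = 4e3)
  src <- source_spec("pencil", origin = cc$origin)
  tally_at <- function(n, seed) {
    fv <- run_simulation(cc$volume, src,
                         sim_config(n_photons = n, seed = seed))
    fv$grid[21, 21, 20] # a mid-depth voxel near the beam
  }
  s1 <- vapply(1:16, function(s) tally_at(4e3, 200 + s), numeric(1))
  s2 <- vapply(1:16, function(s) tally_at(64e3, 300 + s), numeric(1))
  ratio <- sd(s1) / sd(s2) # expect ~ 4 for a 16x photon count
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})
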