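# Shared helpers: small volumes and independent numerical oracles used to
# cross-check the analysis operators.

# a tissue with arbitrary coefficients, bypassing the packaged table
test_tissue <- function(mu_a = 0.02, mu_s = 10, g = 0.9, n = 1.37,
                        name = "test") {
  tissue_properties(name, mu_a = mu_a, mu_s = mu_s, g = g, n = n)
}

# independent FWHM oracle: evaluate a closed-form profile on a very fine
# grid and locate the half crossings by linear interpolation, without using
# the package's fwhm()
oracle_fwhm <- function(f, lo, hi, n = 200001) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  thr <- min(y) + (max(y) - min(y)) / 2
  above <- y >= thr
  idx <- which(above)
  i1 <- min(idx); i2 <- max(idx)
  interp <- function(ia, ib) {
    x[ia] + (thr - y[ia]) / (y[ib] - y[ia]) * (x[ib] - x[ia])
  }
  left <- if (i1 == 1) x[1] else interp(i1 - 1, i1)
  right <- if (i2 == n) x[n] else interp(i2 + 1, i2)
  right - left
}

# independent depth-at-level oracle for a decaying closed-form axial field:
# deepest voxel (half-open convention, centers at (k+0.5)*dx) whose value
# reaches the level, reported as (k+1)*dx
oracle_depth <- function(f, level, nz, dx) {
  centers <- ((seq_len(nz) - 1) + 0.5) * dx
  ok <- which(f(centers) >= level)
  if (!length(ok)) return(NA_real_)
  max(ok) * dx
}
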