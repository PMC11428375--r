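// Voxel Monte Carlo photon transport in a homogeneous absorbing/scattering
// medium: exponential free paths, Henyey-Greenstein scattering, track-length
// fluence estimator with continuous absorption, Fresnel boundary handling,
// Russian roulette. All randomness comes from a self-contained xoshiro256++
// stream so runs are bit-reproducible for a given integer seed.

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops")
#endif

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

static const double C_MM_PER_S = 2.99792458e11; // speed of light, mm/s

// ---------------------------------------------------------------- RNG ------

struct XoshiroRNG {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit XoshiroRNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1]
  double unif() { return ((next() >> 11) + 1) * 1.1102230246251565e-16; }
  // uniform on [0, 1)
  double unif0() { return (next() >> 11) * 1.1102230246251565e-16; }

  double normal() { // Marsaglia polar
    double u, v, r2;
    do {
      u = 2.0 * unif0() - 1.0;
      v = 2.0 * unif0() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 < 1e-300);
    return u * std::sqrt(-2.0 * std::log(r2) / r2);
  }
};

// ------------------------------------------------------------ geometry -----

static inline void vnormalize(double *v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= n; v[1] /= n; v[2] /= n;
}

// Rotate direction d by deflection cos(theta)=ct with uniform azimuth.
static inline void spin_direction(double *d, double ct, XoshiroRNG &rng) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double x, y, r2;
  do { // rejection-sampled azimuth (avoids trig calls)
    x = 2.0 * rng.unif0() - 1.0;
    y = 2.0 * rng.unif0() - 1.0;
    r2 = x * x + y * y;
  } while (r2 > 1.0 || r2 < 1e-12);
  double inv = 1.0 / std::sqrt(r2);
  double cp = x * inv, sp = y * inv;
  if (std::fabs(d[2]) > 0.99999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = ct * (d[2] >= 0 ? 1.0 : -1.0);
  } else {
    double uz = d[2];
    double den = std::sqrt(1.0 - uz * uz);
    double ux = d[0], uy = d[1];
    d[0] = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    d[1] = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    d[2] = -den * st * cp + uz * ct;
  }
  vnormalize(d);
}

// Henyey-Greenstein deflection cosine; first moment equals g.
static inline double hg_cosine(double g, XoshiroRNG &rng) {
  if (std::fabs(g) < 1e-7) return 2.0 * rng.unif0() - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif0());
  double ct = (1.0 + g * g - t * t) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Unpolarized Fresnel reflectance for incidence cosine cos_i, n1 -> n2.
static double fresnel_reflectance(double cos_i, double n1, double n2) {
  cos_i = std::fabs(cos_i);
  if (cos_i > 1.0) cos_i = 1.0;
  double sin_i2 = 1.0 - cos_i * cos_i;
  double ratio = n1 / n2;
  double sin_t2 = ratio * ratio * sin_i2;
  if (sin_t2 >= 1.0) return 1.0; // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// ------------------------------------------------------------- sources -----

enum SourceKind {
  SRC_FIXED = -1,
  SRC_PENCIL = 0, SRC_ISOTROPIC, SRC_CONE, SRC_ARCSINE, SRC_LINE, SRC_SLIT,
  SRC_COLLIMATED_GAUSSIAN, SRC_ANGULAR_GAUSSIAN, SRC_HYPERBOLOID_GAUSSIAN,
  SRC_PLANAR, SRC_DISK, SRC_RING, SRC_PENCIL_ARRAY,
  SRC_FOURIER_SPATIAL, SRC_FOURIER_1D, SRC_FOURIER_2D
};

struct Source {
  int kind;
  double origin[3], axis[3];
  double e1u[3], e2u[3];          // unit transverse basis
  double edge1[3], edge2[3];      // patch / segment edges (mm)
  double waist, half_angle, zenith_sd, focus;
  double inner_r, outer_r, f1, f2, phase, mod;
  int n1, n2;
  double fixed_pos[3], fixed_dir[3], fixed_w;
};

static void get3(const List &src, const char *name, double *out) {
  NumericVector v = src[name];
  out[0] = v[0]; out[1] = v[1]; out[2] = v[2];
}

static Source parse_source(const List &src) {
  Source s;
  std::memset(&s, 0, sizeof(s));
  s.kind = as<int>(src["kind_id"]);
  if (s.kind == SRC_FIXED) {
    get3(src, "position", s.fixed_pos);
    get3(src, "direction", s.fixed_dir);
    vnormalize(s.fixed_dir);
    s.fixed_w = as<double>(src["weight"]);
    return s;
  }
  get3(src, "origin", s.origin);
  get3(src, "axis", s.axis);
  vnormalize(s.axis);
  // transverse basis orthogonal to the axis
  if (std::fabs(s.axis[2]) < 0.999) {
    s.e1u[0] = s.axis[1]; s.e1u[1] = -s.axis[0]; s.e1u[2] = 0.0; // axis x z
  } else {
    s.e1u[0] = 1.0; s.e1u[1] = 0.0; s.e1u[2] = 0.0;
  }
  // orthogonalize and complete the triad
  double dp = s.e1u[0] * s.axis[0] + s.e1u[1] * s.axis[1] + s.e1u[2] * s.axis[2];
  for (int i = 0; i < 3; ++i) s.e1u[i] -= dp * s.axis[i];
  vnormalize(s.e1u);
  s.e2u[0] = s.axis[1] * s.e1u[2] - s.axis[2] * s.e1u[1];
  s.e2u[1] = s.axis[2] * s.e1u[0] - s.axis[0] * s.e1u[2];
  s.e2u[2] = s.axis[0] * s.e1u[1] - s.axis[1] * s.e1u[0];

  if (src.containsElementNamed("edge1")) get3(src, "edge1", s.edge1);
  if (src.containsElementNamed("edge2")) get3(src, "edge2", s.edge2);
  if (src.containsElementNamed("waist")) s.waist = as<double>(src["waist"]);
  if (src.containsElementNamed("half_angle")) s.half_angle = as<double>(src["half_angle"]);
  if (src.containsElementNamed("zenith_variance"))
    s.zenith_sd = std::sqrt(as<double>(src["zenith_variance"]));
  if (src.containsElementNamed("focus_distance")) s.focus = as<double>(src["focus_distance"]);
  if (src.containsElementNamed("inner_radius")) s.inner_r = as<double>(src["inner_radius"]);
  if (src.containsElementNamed("outer_radius")) s.outer_r = as<double>(src["outer_radius"]);
  if (src.containsElementNamed("f1")) s.f1 = as<double>(src["f1"]);
  if (src.containsElementNamed("f2")) s.f2 = as<double>(src["f2"]);
  if (src.containsElementNamed("phase")) s.phase = as<double>(src["phase"]);
  if (src.containsElementNamed("modulation")) s.mod = as<double>(src["modulation"]);
  if (src.containsElementNamed("n1")) s.n1 = as<int>(src["n1"]);
  if (src.containsElementNamed("n2")) s.n2 = as<int>(src["n2"]);
  return s;
}

static inline void isotropic_direction(double *d, XoshiroRNG &rng) {
  double ct = 2.0 * rng.unif0() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double x, y, r2;
  do {
    x = 2.0 * rng.unif0() - 1.0;
    y = 2.0 * rng.unif0() - 1.0;
    r2 = x * x + y * y;
  } while (r2 > 1.0 || r2 < 1e-12);
  double inv = 1.0 / std::sqrt(r2);
  d[0] = st * x * inv; d[1] = st * y * inv; d[2] = ct;
}

// radial offset with Gaussian-beam density p(r) ~ r * exp(-2 r^2 / w^2)
static inline double gaussian_beam_radius(double waist, XoshiroRNG &rng) {
  return waist * std::sqrt(-std::log(rng.unif()) * 0.5);
}

static void sample_launch_one(const Source &s, XoshiroRNG &rng,
                              double *pos, double *dir, double &w) {
  w = 1.0;
  for (int i = 0; i < 3; ++i) { pos[i] = s.origin[i]; dir[i] = s.axis[i]; }
  double r, u, v, cp, sp;
  switch (s.kind) {
  case SRC_FIXED:
    for (int i = 0; i < 3; ++i) { pos[i] = s.fixed_pos[i]; dir[i] = s.fixed_dir[i]; }
    w = s.fixed_w;
    break;
  case SRC_PENCIL:
    break;
  case SRC_ISOTROPIC:
    isotropic_direction(dir, rng);
    break;
  case SRC_CONE: { // uniform over the spherical cap zenith <= half_angle
    double ct = 1.0 - rng.unif0() * (1.0 - std::cos(s.half_angle));
    spin_direction(dir, ct, rng);
    break;
  }
  case SRC_ARCSINE: { // zenith uniform on [0, pi]
    double theta = rng.unif0() * M_PI;
    spin_direction(dir, std::cos(theta), rng);
    break;
  }
  case SRC_LINE:
    u = rng.unif0();
    for (int i = 0; i < 3; ++i) pos[i] = s.origin[i] + u * s.edge1[i];
    isotropic_direction(dir, rng);
    break;
  case SRC_SLIT:
    u = rng.unif0();
    for (int i = 0; i < 3; ++i) pos[i] = s.origin[i] + u * s.edge1[i];
    break;
  case SRC_COLLIMATED_GAUSSIAN:
    r = gaussian_beam_radius(s.waist, rng);
    cp = std::cos(2.0 * M_PI * (u = rng.unif0()));
    sp = std::sin(2.0 * M_PI * u);
    for (int i = 0; i < 3; ++i)
      pos[i] = s.origin[i] + r * (cp * s.e1u[i] + sp * s.e2u[i]);
    break;
  case SRC_ANGULAR_GAUSSIAN: {
    double theta = s.zenith_sd * rng.normal();
    spin_direction(dir, std::cos(theta), rng);
    break;
  }
  case SRC_HYPERBOLOID_GAUSSIAN: {
    // skew ray bundle: launch point at radius r, waist-plane point at the
    // same radius but azimuth + 90 deg, a focus_distance along the axis;
    // the ruled envelope is the hyperboloid of a Gaussian beam
    r = gaussian_beam_radius(s.waist, rng);
    u = rng.unif0();
    cp = std::cos(2.0 * M_PI * u);
    sp = std::sin(2.0 * M_PI * u);
    double wp[3];
    for (int i = 0; i < 3; ++i) {
      pos[i] = s.origin[i] + r * (cp * s.e1u[i] + sp * s.e2u[i]);
      wp[i] = s.origin[i] + s.focus * s.axis[i] +
              r * (-sp * s.e1u[i] + cp * s.e2u[i]);
      dir[i] = wp[i] - pos[i];
    }
    vnormalize(dir);
    break;
  }
  case SRC_PLANAR:
    u = rng.unif0(); v = rng.unif0();
    for (int i = 0; i < 3; ++i)
      pos[i] = s.origin[i] + u * s.edge1[i] + v * s.edge2[i];
    break;
  case SRC_DISK:
    r = s.outer_r * std::sqrt(rng.unif0());
    cp = std::cos(2.0 * M_PI * (u = rng.unif0()));
    sp = std::sin(2.0 * M_PI * u);
    for (int i = 0; i < 3; ++i)
      pos[i] = s.origin[i] + r * (cp * s.e1u[i] + sp * s.e2u[i]);
    break;
  case SRC_RING:
    r = std::sqrt(s.inner_r * s.inner_r +
                  rng.unif0() * (s.outer_r * s.outer_r - s.inner_r * s.inner_r));
    cp = std::cos(2.0 * M_PI * (u = rng.unif0()));
    sp = std::sin(2.0 * M_PI * u);
    for (int i = 0; i < 3; ++i)
      pos[i] = s.origin[i] + r * (cp * s.e1u[i] + sp * s.e2u[i]);
    break;
  case SRC_PENCIL_ARRAY: {
    int i1 = (int)(rng.unif0() * s.n1); if (i1 >= s.n1) i1 = s.n1 - 1;
    int i2 = (int)(rng.unif0() * s.n2); if (i2 >= s.n2) i2 = s.n2 - 1;
    double fu = s.n1 > 1 ? (double)i1 / (s.n1 - 1) : 0.5;
    double fv = s.n2 > 1 ? (double)i2 / (s.n2 - 1) : 0.5;
    for (int i = 0; i < 3; ++i)
      pos[i] = s.origin[i] + fu * s.edge1[i] + fv * s.edge2[i];
    break;
  }
  case SRC_FOURIER_SPATIAL:
  case SRC_FOURIER_1D: {
    u = rng.unif0(); v = rng.unif0();
    double f2 = (s.kind == SRC_FOURIER_1D) ? 0.0 : s.f2;
    for (int i = 0; i < 3; ++i)
      pos[i] = s.origin[i] + u * s.edge1[i] + v * s.edge2[i];
    w = 0.5 * (1.0 + s.mod * std::cos(2.0 * M_PI * (s.f1 * u + f2 * v) + s.phase));
    if (w < 0.0) w = 0.0; if (w > 1.0) w = 1.0;
    break;
  }
  case SRC_FOURIER_2D:
    u = rng.unif0(); v = rng.unif0();
    for (int i = 0; i < 3; ++i)
      pos[i] = s.origin[i] + u * s.edge1[i] + v * s.edge2[i];
    w = 0.25 * (1.0 + std::cos(2.0 * M_PI * s.f1 * u)) *
              (1.0 + std::cos(2.0 * M_PI * s.f2 * v));
    break;
  default:
    stop("unknown source kind id %d", s.kind);
  }
}

// -------------------------------------------------------------- medium -----

struct Medium {
  int nx, ny, nz;
  double dx;                    // voxel edge, mm
  double Lx, Ly, Lz;            // physical extents, mm
  double mua, mus, mut, g;
  double n_tissue, ambient_n;
};

struct Tallies {
  double launched = 0.0, absorbed = 0.0, escaped = 0.0, expired = 0.0;
  double roulette_boost = 0.0;
  double clipped = 0.0;         // launches resampled for falling off the face
  double steps = 0.0, segments = 0.0; // walk-effort counters (diagnostics)
};

// Deposit a straight sub-path of length len starting at p along d, splitting
// at voxel boundaries (DDA); attenuates w continuously by absorption and
// accumulates the track-length fluence integral per voxel. Advances p.
// inv_d caches 1/d (+-inf where d ~ 0) so plane distances cost a multiply.
static inline double deposit_path_fast(double *grid, const Medium &m,
                                       double *p, const double *d,
                                       const double *inv_d, double len,
                                       double w, double &absorbed) {
  const double push = 1e-9; // nudge across voxel planes, mm
  const double inv_dx = 1.0 / m.dx;
  double remaining = len;
  while (remaining > 1e-12) {
    int ix = (int)(p[0] * inv_dx); if (ix < 0) ix = 0; if (ix >= m.nx) ix = m.nx - 1;
    int iy = (int)(p[1] * inv_dx); if (iy < 0) iy = 0; if (iy >= m.ny) iy = m.ny - 1;
    int iz = (int)(p[2] * inv_dx); if (iz < 0) iz = 0; if (iz >= m.nz) iz = m.nz - 1;
    double t = remaining;
    double q;
    q = (((inv_d[0] > 0.0 ? ix + 1 : ix) * m.dx) - p[0]) * inv_d[0];
    if (q < t) t = q;
    q = (((inv_d[1] > 0.0 ? iy + 1 : iy) * m.dx) - p[1]) * inv_d[1];
    if (q < t) t = q;
    q = (((inv_d[2] > 0.0 ? iz + 1 : iz) * m.dx) - p[2]) * inv_d[2];
    if (q < t) t = q;
    if (t < 0.0) t = 0.0;
    double l = t + push;
    if (l > remaining) l = remaining;
    double dep, att;
    double x = m.mua * l;
    if (x < 1e-5) { // series forms avoid exp() in the common fine-step case
      dep = w * l * (1.0 - 0.5 * x + x * x / 6.0);
      att = 1.0 - x + 0.5 * x * x;
    } else {
      att = std::exp(-x);
      dep = w * (1.0 - att) / m.mua;
    }
    grid[ix + (size_t)m.nx * (iy + (size_t)m.ny * iz)] += dep;
    absorbed += w * (1.0 - att);
    w *= att;
    p[0] += l * d[0]; p[1] += l * d[1]; p[2] += l * d[2];
    remaining -= l;
  }
  return w;
}

static inline void cache_inv(const double *d, double *inv_d) {
  for (int a = 0; a < 3; ++a) {
    inv_d[a] = (std::fabs(d[a]) > 1e-12) ? 1.0 / d[a]
               : (d[a] >= 0 ? 1e300 : -1e300);
  }
}

// compatibility wrapper for the exported single-track deposit
static inline double deposit_path(double *grid, const Medium &m,
                                  double *p, const double *d, double len,
                                  double w, double &absorbed) {
  double inv_d[3];
  cache_inv(d, inv_d);
  return deposit_path_fast(grid, m, p, d, inv_d, len, w, absorbed);
}

// Trace one photon to completion, updating grid and tallies.
static void trace_photon(double *grid, const Medium &m, const Source &src,
                         XoshiroRNG &rng, Tallies &tal,
                         double end_time, double r_thresh, double r_surv,
                         bool reflect) {
  double p[3], d[3], w;
  sample_launch_one(src, rng, p, d, w);
  if (src.kind >= 0) {
    // clip patch sources to the entry face: resample launches landing outside
    int tries = 0;
    while ((p[0] < 0.0 || p[0] > m.Lx || p[1] < 0.0 || p[1] > m.Ly ||
            p[2] < 0.0 || p[2] > m.Lz) && tries < 1000) {
      sample_launch_one(src, rng, p, d, w);
      ++tries; tal.clipped += 1.0;
    }
    if (tries >= 1000) stop("source geometry lies outside the volume face");
  }
  tal.launched += w;
  if (w <= 0.0) { tal.absorbed += 0.0; return; } // zero-weight pattern launch

  double elapsed = 0.0;
  double time_per_mm = m.n_tissue / C_MM_PER_S;
  double inv_mut = 1.0 / m.mut;
  double s_left = -std::log(rng.unif()) * inv_mut;
  double p_scatter = m.mus / m.mut;
  double inv_d[3];
  cache_inv(d, inv_d);

  for (;;) {
    // distance to the volume boundary along d
    double t_exit = 1e300; int exit_axis = -1;
    const double L[3] = { m.Lx, m.Ly, m.Lz };
    for (int a = 0; a < 3; ++a) {
      double q = ((inv_d[a] > 0.0 ? L[a] : 0.0) - p[a]) * inv_d[a];
      if (q < t_exit) { t_exit = q; exit_axis = a; }
    }
    if (t_exit < 0.0) t_exit = 0.0;
    bool hits = (t_exit <= s_left);
    double seg = hits ? t_exit : s_left;

    // clip the segment at the time gate: deposit only the in-gate part
    double t_dist = (end_time - elapsed) / time_per_mm;
    bool expires = (seg > t_dist);
    double seg_eff = expires ? (t_dist > 0.0 ? t_dist : 0.0) : seg;

    tal.steps += 1.0;
    w = deposit_path_fast(grid, m, p, d, inv_d, seg_eff, w, tal.absorbed);
    elapsed += seg_eff * time_per_mm;
    if (expires) { tal.expired += w; return; }

    if (hits) {
      double R = reflect ? fresnel_reflectance(d[exit_axis], m.n_tissue, m.ambient_n)
                         : 0.0;
      if (R >= 1.0 || (R > 0.0 && rng.unif0() < R)) {
        d[exit_axis] = -d[exit_axis];
        inv_d[exit_axis] = -inv_d[exit_axis];
        // fold any numerical overshoot back inside
        if (p[exit_axis] < 0.0) p[exit_axis] = -p[exit_axis];
        if (p[exit_axis] > L[exit_axis]) p[exit_axis] = 2.0 * L[exit_axis] - p[exit_axis];
        s_left -= seg;
        if (s_left > 1e-12) continue;
        // step ended exactly at the wall: fall through to the interaction
      } else {
        tal.escaped += w;
        return;
      }
    } else {
      s_left = 0.0;
    }

    // interaction at the step end: scatter with probability mus/mut,
    // otherwise the collision is null and the photon continues straight
    if (p_scatter >= 1.0 || rng.unif0() < p_scatter) {
      spin_direction(d, hg_cosine(m.g, rng), rng);
      cache_inv(d, inv_d);
    }
    if (w < r_thresh) { // Russian roulette
      if (rng.unif0() < r_surv) {
        double w_new = w / r_surv;
        tal.roulette_boost += w_new - w;
        w = w_new;
      } else {
        tal.absorbed += w; // killed weight booked as absorbed-equivalent
        return;
      }
    }
    s_left = -std::log(rng.unif()) * inv_mut;
  }
}

static Medium make_medium(IntegerVector shape, double voxel_size,
                          double mua, double mus, double g,
                          double n_tissue, double ambient_n) {
  Medium m;
  m.nx = shape[0]; m.ny = shape[1]; m.nz = shape[2];
  m.dx = voxel_size;
  m.Lx = m.nx * voxel_size; m.Ly = m.ny * voxel_size; m.Lz = m.nz * voxel_size;
  m.mua = mua; m.mus = mus; m.mut = mua + mus; m.g = g;
  m.n_tissue = n_tissue; m.ambient_n = ambient_n;
  if (m.mut <= 0.0) stop("mu_a + mu_s must be positive");
  return m;
}

// [[Rcpp::export]]
List cpp_run_simulation(IntegerVector shape, double voxel_size,
                        double mua, double mus, double g,
                        double n_tissue, double ambient_n,
                        List source, double n_photons,
                        double end_time, double roulette_threshold,
                        double roulette_survival, bool reflect_at_boundary,
                        double seed) {
  Medium m = make_medium(shape, voxel_size, mua, mus, g, n_tissue, ambient_n);
  Source src = parse_source(source);
  XoshiroRNG rng((uint64_t)seed);
  size_t nvox = (size_t)m.nx * m.ny * m.nz;
  NumericVector grid(nvox);
  double *gp = REAL(grid);
  Tallies tal;
  R_xlen_t n = (R_xlen_t)n_photons;
  for (R_xlen_t i = 0; i < n; ++i) {
    trace_photon(gp, m, src, rng, tal, end_time,
                 roulette_threshold, roulette_survival, reflect_at_boundary);
    if ((i & 0xFFFFF) == 0xFFFFF) Rcpp::checkUserInterrupt();
  }
  grid.attr("dim") = shape;
  return List::create(_["fluence_raw"] = grid,
                      _["launched"] = tal.launched,
                      _["absorbed"] = tal.absorbed,
                      _["escaped"] = tal.escaped,
                      _["expired"] = tal.expired,
                      _["roulette_boost"] = tal.roulette_boost,
                      _["clipped"] = tal.clipped,
                      _["steps"] = tal.steps,
                      _["segments"] = tal.segments,
                      _["n_photons"] = (double)n);
}

// [[Rcpp::export]]
List cpp_sample_launch(List source, int n, double seed,
                       NumericVector volume_extent) {
  Source src = parse_source(source);
  XoshiroRNG rng((uint64_t)seed);
  NumericMatrix pos(n, 3), dir(n, 3);
  NumericVector wt(n);
  double p[3], d[3], w;
  double clipped = 0.0;
  bool have_vol = volume_extent.size() == 3;
  for (int i = 0; i < n; ++i) {
    sample_launch_one(src, rng, p, d, w);
    if (have_vol && src.kind >= 0) {
      int tries = 0;
      while ((p[0] < 0.0 || p[0] > volume_extent[0] ||
              p[1] < 0.0 || p[1] > volume_extent[1] ||
              p[2] < 0.0 || p[2] > volume_extent[2]) && tries < 1000) {
        sample_launch_one(src, rng, p, d, w);
        ++tries; clipped += 1.0;
      }
      if (tries >= 1000) stop("source geometry lies outside the volume face");
    }
    for (int k = 0; k < 3; ++k) { pos(i, k) = p[k]; dir(i, k) = d[k]; }
    wt[i] = w;
  }
  return List::create(_["position"] = pos, _["direction"] = dir,
                      _["weight"] = wt, _["clipped"] = clipped);
}

// [[Rcpp::export]]
NumericVector cpp_sample_step(int n, double mu_t, double seed) {
  if (mu_t <= 0.0) stop("mu_t must be positive");
  XoshiroRNG rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = -std::log(rng.unif()) / mu_t;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_scatter_direction(NumericVector direction, double g,
                                    int n, double seed) {
  XoshiroRNG rng((uint64_t)seed);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double d[3] = { direction[0], direction[1], direction[2] };
    vnormalize(d);
    spin_direction(d, hg_cosine(g, rng), rng);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_deposit_track(NumericVector grid, IntegerVector shape,
                       double voxel_size, NumericVector start,
                       NumericVector end, double weight_in, double mua) {
  Medium m = make_medium(shape, voxel_size, mua, 1.0, 0.0, 1.0, 1.0);
  m.mua = mua; // make_medium demanded mut > 0; deposit only uses mua
  NumericVector g2 = clone(grid);
  double p[3] = { start[0], start[1], start[2] };
  double d[3] = { end[0] - start[0], end[1] - start[1], end[2] - start[2] };
  double len = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (len > 0) { d[0] /= len; d[1] /= len; d[2] /= len; }
  double absorbed = 0.0;
  double w_out = deposit_path(REAL(g2), m, p, d, len, weight_in, absorbed);
  g2.attr("dim") = shape;
  return List::create(_["grid"] = g2, _["weight_out"] = w_out,
                      _["absorbed"] = absorbed);
}

// [[Rcpp::export]]
double cpp_fresnel_reflectance(double cos_i, double n1, double n2) {
  return fresnel_reflectance(cos_i, n1, n2);
}
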