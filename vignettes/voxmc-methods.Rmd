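---
title: "Photon transport in single-layer brain tissue: model and methods"
author: "voxmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon transport in single-layer brain tissue: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxmc)
```

## The question the package addresses

Choosing an illumination geometry is a practical design decision in
near-infrared brain imaging — in particular photoacoustic imaging, where the
absorbed optical energy is the signal source. Multi-layer head models couple
the effect of the source geometry to the layer structure; simulating each
tissue as its own homogeneous block isolates how a given source behaves in
*that* tissue. `voxmc` implements this single-layer study end to end: a
voxel Monte Carlo transport engine, sixteen optical source geometries, and
the two summary metrics used to compare them — axial penetration depth at
fixed normalized-energy levels, and lateral full width at half maximum
(FWHM).

## Physical model

Each simulation volume is a homogeneous cube (default $140^3$ voxels of
0.1 mm, i.e. $14\times14\times14$ mm) of one tissue characterized by four
coefficients at 800 nm: absorption $\mu_a$ (mm$^{-1}$), scattering $\mu_s$
(mm$^{-1}$), the Henyey–Greenstein anisotropy $g$ (the mean cosine of the
scattering deflection), and refractive index $n$. The packaged table covers
scalp, skull, cerebrospinal fluid (CSF), gray matter, white matter and blood
vessel:

```{r}
tissue_table()
```

Photons random-walk through the cube:

* **Free paths** are exponential at the total attenuation rate,
  $s = -\ln \xi / \mu_t$ with $\mu_t = \mu_a + \mu_s$. At each step end the
  collision is a true scattering event with probability $\mu_s/\mu_t$ and a
  null collision otherwise (a thinning construction; the scattering event
  rate is exactly $\mu_s$).
* **Scattering** draws the deflection cosine from the Henyey–Greenstein
  distribution, whose first moment equals $g$; the azimuth is uniform.
* **Absorption** is continuous along every traversed segment (track-length
  estimator): a segment of length $\ell$ entered with weight $w$ adds
  $w\,(1-e^{-\mu_a \ell})/\mu_a$ to the voxel's fluence integral and leaves
  with weight $w\,e^{-\mu_a \ell}$. This is unbiased for fluence and keeps
  variance low in weak absorbers such as CSF ($\mu_a = 0.004$ mm$^{-1}$),
  where interaction-based deposition would be sparse. Absorption
  $A = \mu_a F$ follows voxelwise, so normalized absorption and normalized
  fluence are the same map.
* **Boundaries**: at a cube face the unpolarized Fresnel reflectance for the
  tissue-to-ambient index step (ambient $n = 1$, air, configurable) decides
  between specular reflection and escape; incidence beyond the critical
  angle reflects totally. Reflection can be disabled
  (`reflect_at_boundary = FALSE`), in which case every face crossing
  escapes.
* **Termination**: escape, the 50 ns time gate (path length is converted to
  time at speed $c/n$; at these length scales the gate is effectively
  non-binding and is kept for fidelity to the study configuration), or
  Russian roulette once the weight falls below $10^{-4}$: survival with
  probability 0.1 and reweighting by 10 keeps termination unbiased; killed
  weight is booked on the absorbed side of the conservation ledger, and the
  reweighting credit is tracked so that
  launched + credit = absorbed + escaped + expired holds to floating-point
  accuracy on every run (`conservation_residual()`).

One `xoshiro256++` stream drives both source sampling and transport, so an
integer seed fixes a run bit-exactly.

## Source geometries

All sixteen sources launch from the $z=0$ face centered on
$(x,y) = (7,7)$ mm and aim along $+z$. The study that defined this
source set did not print the per-type numeric parameters (waist radii,
angles, patch sizes, spatial frequencies), so those live in one versioned
YAML (`inst/extdata/source_defaults.yaml`) as the package's frozen study
configuration rather than in code. The defaults follow the conventions of
the voxel-MC source taxonomy this set comes from: a 1 mm $1/e^2$ waist for
the collimated Gaussian beam (0.6 mm with a 2 mm focus distance for the
hyperboloid bundle), a $\pi/6$ cone half-angle, millimetre-scale apertures
for the extended sources (a $1\times1$ mm patch — 10 units of the 0.1 mm
voxel raster — for the planar, array and Fourier sources, a 0.5 mm disk, a
0.2–0.4 mm annulus, a 1 mm line/slit segment), one cycle per patch for the
Fourier patterns, and a $4\times4$ pencil array. The millimetre scale of
the extended apertures is fixed by two published observations: the
near-surface lateral field widths are below 1 mm for every source, and the
deepest-penetrating trio is collimated Gaussian, then planar, then disk,
which pins the aperture spreads below the collimated beam's. Three conventions are worth noting:

* The **line** and **slit** share a 1 mm segment oriented along $y$ (the
  line emits isotropically, the slit stays collimated); the $y$ orientation
  reproduces the observed asymmetry of the line source between the two
  lateral axes.
* The **Fourier-patterned** patches modulate the *initial weight* of each
  launch — $\tfrac12(1+M\cos(2\pi(f_1u+f_2v)+\phi))$ for the spatial and 1D
  patterns, the separable product form for the 2D pattern — rather than
  rejection-sampling positions; this matches the deposit-tally semantics
  and has lower variance. The default spatial-frequency pattern is a
  half-cycle diagonal ($f_1=f_2=0.5$, phase 0): a pattern null on the beam
  axis with crests at two patch corners, which reproduces the reported
  behavior that this source's axial column stays far below the levels the
  bright-centered sources reach. The 1D pattern uses phase $\pi$, placing
  a crest on the axis so it behaves like the bright extended sources.
* The **hyperboloid Gaussian** is built as a skew ray bundle: a launch
  point at Gaussian-distributed radius $r$ and a waist-plane point at the
  same radius but azimuth rotated by $90^\circ$, a focus distance (default
  2 mm) down the axis. The ruled envelope of such skew rays is the
  hyperboloid of a Gaussian beam, with the true waist $r/\sqrt2$ at half
  the focus distance; past the waist the bundle diverges, which is why this
  source produces both competitive axial depth and the largest deep-slice
  FWHM.

Patch sources whose footprint leaves the entry face are clipped by
resampling, with a warning.

## Analysis conventions

Positions are continuous in mm; voxel $i$ (0-based) covers
$[i\Delta,(i+1)\Delta)$. The study line $x=y=7$ mm therefore maps to the
single voxel column $(70,70)$, unambiguously.

* **Normalization** rescales a volume to $[0,100]$ from its global extrema,
  $E_N = (E-E_{\min})/(E_{\max}-E_{\min})\times100$; a constant field is an
  error.
* **Depth at level $L$** is the depth of the deepest voxel on the axial
  column whose normalized value reaches $L$ — levels are percentages *of
  the volume maximum* (i.e. thresholds on the normalized value itself), not
  of the per-column maximum. This choice is forced by the observed
  phenomenon of a source whose axial column never reaches the 1% level,
  which is only possible against the volume-wide reference. Depth is
  reported as $(i+1)\Delta$ so a column that qualifies over its whole
  length reports the full 14.0 mm; a column that never qualifies reports
  `NA` rather than zero.
* **FWHM** of a lateral profile uses the threshold
  $p_{\min} + (p_{\max}-p_{\min})/2$; crossings are linearly interpolated
  between the last sample at or above the threshold and the first below
  it, walking outward from the peak. Printed widths at 0.1 mm resolution
  imply sub-sample handling; linear interpolation is the minimal
  assumption. A side that never falls to half is bounded at the profile
  edge and *flagged* censored, never silently truncated. The reference
  slice for the headline comparison is the one containing 12 mm — 0-based
  index 120 under the half-open convention.
* **Ranking** sorts sources by the metric; ties are broken by the number of
  sibling conditions (other levels or the other axis) in which the tied
  source attains the best value, and residual ties by the fixed 1–16
  source numbering. Report tables round to 0.1 mm; raw values are kept
  alongside.

A worked example on the reduced configuration:

```{r, eval = FALSE}
vol <- make_volume(builtin_tissue("scalp"))
fv  <- run_simulation(vol, default_sources()$collimated_gaussian,
                      sim_config(n_photons = 2e5, seed = 1))
nv  <- normalize_energy(fv)
max_depth_at_level(axial_profile(nv), 1)     # ~5.5 mm
fwhm(lateral_profile(nv, "x", 6))$width      # ~4.9 mm
```

## Synthetic fixtures and what they do (not) show

`analytic_volume()` builds smooth closed-form fields — an axially
exponential beam, fixed and widening lateral Gaussians, constant and
single-voxel fields — evaluated at voxel centers, so every analysis
operator can be checked against an exact answer (`tau * log(100/L)` for the
depth, $2\sqrt{2\ln2}\,\sigma$ for the FWHM) independently of the transport
engine. They carry no Monte Carlo noise and no speckle, so they validate
the *operators*, not the statistics of real simulations; the transport
engine itself is audited by its own invariants (conservation,
Beer–Lambert decay with scattering disabled, Henyey–Greenstein moment
recovery, $1/\sqrt{n}$ tally noise). `ci_config()` pairs a 4 mm cube with
$10^5$ photons for second-scale checks.

## Numerical choices

* Exponential attenuation over sub-voxel segments uses third-order series
  forms below $\mu_a\ell < 10^{-5}$ (relative error $<10^{-16}$),
  avoiding `exp()` in the common fine-step case.
* Voxel traversal nudges $10^{-9}$ mm across each plane crossing to avoid
  stalls on exact boundaries; segment bookkeeping is exact, so
  conservation residuals stay at the $10^{-13}$ level.
* Azimuths are sampled by rejection from the unit disk (no trigonometric
  calls); directions are renormalized after every rotation.
* Degenerate inputs error early: unknown tissue or source kind, missing
  source parameters (named in the message), constant fields, all-equal
  profiles, out-of-range coordinates and levels.

## Problem sizes

The full study configuration is $10^8$ photons per tissue–source cell. The
package's own test and reproduction runs use reduced counts, chosen so
each check is comfortably inside its sampling tolerance: $10^4$–$10^5$
photons for engine invariants, $5\times10^5$–$4\times10^6$ per cell for the
depth and deep-slice FWHM reproductions (the 1%-level depth estimate is
stable to about ±0.2 mm from $\approx5\times10^5$ photons in the strongly
scattering tissues), and $10^5$ per cell for the 96-cell sweep scripts. Deep-tail quantities (the 0.01% level) converge
from above as the photon count grows, because threshold crossings ride on
the noise floor; this is visible when comparing reduced runs to the
published full-scale values. Two cases are intrinsically the most
noise-sensitive and get the largest counts: the cerebrospinal-fluid 1%
depth (its axial profile is nearly flat where it crosses the threshold, so
a small value fluctuation moves the crossing by several voxels) and the
white-matter 0.01% depth (a deep-tail threshold).

## Known limitations

* Homogeneous single-layer volumes only; no interior interfaces or
  multi-layer head geometry (the volume type records its shape so an
  extension is possible, but it is untested).
* Henyey–Greenstein is the only phase function; one wavelength (800 nm)
  of optical properties ships with the package.
* The per-source numeric parameters are conventions frozen in the packaged
  YAML, not values fitted to hardware; FWHM extremes for the strongly
  parameter-dependent sources (hyperboloid Gaussian, Fourier patterns)
  shift with those choices.
* Fluence is integrated over a single time gate; no time-resolved output.
* Volumes persist as RDS with a JSON manifest sidecar; no HDF5/NRRD
  bindings exist in this R environment, and the round trip is bit-exact.
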