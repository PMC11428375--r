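Package: voxmc
Title: Voxel Monte Carlo Photon Transport in Single-Layer Brain Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seeded voxel Monte Carlo simulation of near-infrared photon
    transport (800 nm) through homogeneous brain-tissue cubes (scalp, skull,
    cerebrospinal fluid, gray matter, white matter, blood vessel), with a
    track-length fluence estimator, Henyey-Greenstein scattering, Fresnel
    boundary handling and Russian roulette. Sixteen configurable optical
    source geometries (pencil through Fourier-patterned patches) are
    sampled on the entry face, and the resulting energy maps are reduced to
    axial penetration depth at fixed normalized-energy levels and lateral
    full width at half maximum, including the full tissue-by-source study
    sweep and its summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
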