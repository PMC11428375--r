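# Packaged default geometry for the sixteen optical source types.
# Positions in mm on the z = 0 entry face of the 14 x 14 x 14 mm cube; the
# beam axis points along +z. The numeric parameters (waists, angles, patch
# size, frequencies, array counts) are the frozen package defaults for the
# study configuration, calibrated once against the published penetration
# table and then fixed; change them here, not in code. Extended sources are
# millimetre-scale apertures (10 grid units of the 0.1 mm voxel raster),
# consistent with the sub-millimetre near-surface field widths of the study.
schema_version: 2
origin_mm: [7, 7, 0]
axis: [0, 0, 1]
sources:
  pencil: {}
  isotropic: {}
  cone:
    half_angle: 0.5235987755982988   # pi/6 rad
  arcsine: {}
  line:                              # 1 mm segment along y, isotropic emission
    origin: [7, 6.5, 0]
    edge1: [0, 1, 0]
  slit:                              # same segment, collimated along +z
    origin: [7, 6.5, 0]
    edge1: [0, 1, 0]
  collimated_gaussian:
    waist: 1.0                       # mm, 1/e^2 intensity radius
  angular_gaussian:
    zenith_variance: 0.25            # rad^2 (sd 0.5 rad)
  hyperboloid_gaussian:
    waist: 0.6                       # mm at the launch plane
    focus_distance: 2.0              # mm along the axis
  planar:                            # 1 x 1 mm patch centered on (7,7)
    origin: [6.5, 6.5, 0]
    edge1: [1, 0, 0]
    edge2: [0, 1, 0]
  disk:
    outer_radius: 0.5                # mm
  ring:
    inner_radius: 0.2                # mm
    outer_radius: 0.4                # mm
  pencil_array:                      # 4 x 4 grid over the 1 x 1 mm patch
    origin: [6.5, 6.5, 0]
    edge1: [1, 0, 0]
    edge2: [0, 1, 0]
    n1: 4
    n2: 4
  fourier_spatial:                   # half-cycle pattern: null on (7,7),
    origin: [6.5, 6.5, 0]            # bright crests at two patch corners
    edge1: [1, 0, 0]
    edge2: [0, 1, 0]
    f1: 0.5
    f2: 0.5
    phase: 0.0
    modulation: 1.0
  fourier_1d:                        # phase pi puts a pattern crest on (7,7)
    origin: [6.5, 6.5, 0]
    edge1: [1, 0, 0]
    edge2: [0, 1, 0]
    f1: 1.0
    phase: 3.141592653589793
    modulation: 1.0
  fourier_2d:
    origin: [6.5, 6.5, 0]
    edge1: [1, 0, 0]
    edge2: [0, 1, 0]
    f1: 1.0
    f2: 1.0
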