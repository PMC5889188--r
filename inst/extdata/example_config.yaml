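# Example run configuration for the whiskerbeam CLI.
# Lengths in the geometry block use the explicit unit keys below;
# everything else is SI.
geometry:
  L: 18            # extrapolated length, virtual tip -> base
  R: 37            # base radius
  trunc: 0.9       # real (trimmed) tip position
  length_unit: mm  # applies to L and trunc
  radius_unit: um  # applies to R
  rho: 1000        # kg/m^3
  E: 3.0e+9        # Pa
  alpha: 430       # rad/s
contact:
  c_frac: 0.6      # pole position as a fraction of L (measured from the tip)
force:
  kind: gaussian_smooth
  F_max: 1.0e-6    # N
  t_f: 0.010       # contact duration, s
  tau: 1.0e-4      # smooth-onset duration, s
  C: 0.5           # Gaussian cutoff
solver:
  n_modes: 60
  dt: 1.0e-5       # output time step, s
  seed: 1
output:
  dir: whiskerbeam_out
  formats: [csv]
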