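case_id: static_droplet
layout:
  name: box
  depth: 0.0001
  disc_radius: .na.real
  channel:
    width: 0.0002
    height: 0.0001
    length: 0.0002
  segments:
  - x0: 0.0
    y0: 0.0001
    x1: 0.0002
    y1: 0.0001
    width: 0.0002
  prefill: ~
  ports: []
  meta: []
fluids:
  continuous:
    density: 908.700000000000045
    viscosity: 0.0643
    name: silicone oil
  dispersed:
    density: 997.0
    viscosity: 0.001003
    name: water
  sigma: 0.01426
  theta_dispersed: 112.0
  theta_continuous: 26.440000000000001
rotation:
  omega_final: 0.0
  t_ramp: 0.0
  sense: 1.0
numerics:
  dx: 2.5e-06
  cfl: 0.4
  capillary_safety: 0.9
  p_tol: 1.0e-09
  max_outer: 50.0
  residual_tol: 1.0e-06
  alpha_clip: 1.0e-08
  dt_max: 1.0e-05
  strict_dt: no
  hs_friction: no
  n_corrector: 2.0
  smooth_passes: 2.0
inlets: []
run:
  t_end: 5.0e-05
  snapshot_dt: 5.0e-05
meta:
  droplet_radius: 5.0e-05
  center:
  - 0.0001
  - 0.0001

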