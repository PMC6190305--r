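case_id: patch_advection
layout:
  name: channel
  depth: 0.0001
  disc_radius: .na.real
  channel:
    width: 0.0004
    height: 0.0001
    length: 0.002
  segments:
  - x0: 0.0
    y0: 0.0
    x1: 0.002
    y1: 0.0
    width: 0.0004
  prefill: ~
  ports:
  - name: inlet_cp
    kind: inlet_cp
    center:
    - 0.0
    - 0.0
    normal:
    - -1.0
    - 0.0
    width: 0.0004
    outlet_id: .na.character
  - name: outlet_a
    kind: outlet
    center:
    - 0.002
    - 0.0
    normal:
    - 1.0
    - 0.0
    width: 0.0004
    outlet_id: A
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
  dx: 2.0e-05
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
inlets:
  cp:
    mode: fixed
    velocity: 0.05
run:
  t_end: 0.001
  snapshot_dt: 0.001
meta: []

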