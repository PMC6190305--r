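case_id: rotating_channel
layout:
  name: radial_expansion
  depth: 0.0001
  disc_radius: .na.real
  channel:
    width: 0.0002
    height: 0.0001
    length: 0.001
  segments:
  - x0: 0.03
    y0: 0.0
    x1: 0.031
    y1: 0.0
    width: 0.0002
  - x0: 0.031
    y0: 0.0
    x1: 0.0318
    y1: 0.0
    width: 0.0006
  prefill: ~
  ports:
  - name: inlet_cp
    kind: inlet_cp
    center:
    - 0.03
    - 0.0
    normal:
    - -1.0
    - 0.0
    width: 0.0002
    outlet_id: .na.character
  - name: outlet_a
    kind: outlet
    center:
    - 0.0318
    - 0.0
    normal:
    - 1.0
    - 0.0
    width: 0.0006
    outlet_id: A
  meta:
    W_chamber: 0.0006
    chamber_start: 0.031
    chamber_length: 0.0008
fluids:
  continuous:
    density: 997.0
    viscosity: 0.001003
    name: water
  dispersed:
    density: 908.700000000000045
    viscosity: 0.0643
    name: silicone oil
  sigma: 0.01426
  theta_dispersed: 68.0
  theta_continuous: ~
rotation:
  omega_final: 150.0
  t_ramp: 0.0002
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
    velocity: 0.02
run:
  t_end: 0.003
  snapshot_dt: 0.0003
meta: []

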