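case_id: validation_40Hz
layout:
  name: validation
  depth: 0.0002
  disc_radius: .na.real
  channel:
    width: 0.00066
    height: 0.0002
    length: 0.025
  segments:
  - x0: 0.031
    y0: 0.0
    x1: 0.057
    y1: 0.0
    width: 0.00066
  - x0: 0.057
    y0: 0.0
    x1: 0.059
    y1: 0.0
    width: 0.000376
  - x0: 0.0317395277335
    y0: 0.001477211629518
    x1: 0.032
    y1: 0.0
    width: 0.000376
  prefill:
  - x0: 0.0317395277335
    y0: 0.001477211629518
    x1: 0.031941812096366
    y1: 0.00033
    width: 0.000376
  ports:
  - name: inlet_cp
    kind: inlet_cp
    center:
    - 0.031
    - 0.0
    normal:
    - -1.0
    - 0.0
    width: 0.00066
    outlet_id: .na.character
  - name: inlet_dp
    kind: inlet_dp
    center:
    - 0.0317395277335
    - 0.001477211629518
    normal:
    - -0.17364817766693
    - 0.984807753012208
    width: 0.000376
    outlet_id: .na.character
  - name: outlet_a
    kind: outlet
    center:
    - 0.059
    - 0.0
    normal:
    - 1.0
    - 0.0
    width: 0.000376
    outlet_id: A
  meta:
    r_junction: 0.032
    junction_angle: 80.0
    W_constriction: 0.000376
fluids:
  continuous:
    density: 909.0
    viscosity: 0.0622
    name: sunflower oil
  dispersed:
    density: 1005.0
    viscosity: 0.00109
    name: water
  sigma: 0.02833
  theta_dispersed: 82.700000000000003
  theta_continuous: 10.300000000000001
rotation:
  omega_final: 251.327412287183449
  t_ramp: 0.01
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
  hs_friction: yes
  n_corrector: 2.0
  smooth_passes: 2.0
inlets:
  cp:
    mode: fixed
    velocity: 0.0729
  dp:
    mode: fixed
    velocity: 0.05
run:
  t_end: 0.05
  snapshot_dt: 0.001
meta:
  r_eval: 0.032
  bo_printed: 0.25

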