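case_id: device
layout:
  name: device
  depth: 0.0001
  disc_radius: 0.054
  channel:
    width: 0.0002
    height: 0.0001
    length: 0.017
  segments:
  - x0: 0.015
    y0: 0.0
    x1: 0.032
    y1: 0.0
    width: 0.0002
  - x0: 0.024
    y0: 0.0
    x1: 0.024
    y1: 0.004
    width: 0.0002
  - x0: 0.0229
    y0: 0.001
    x1: 0.024
    y1: 0.001
    width: 0.0002
  - x0: 0.024
    y0: 0.004
    x1: 0.0261
    y1: 0.004
    width: 0.0002
  - x0: 0.024
    y0: 0.004
    x1: 0.024
    y1: 0.0061
    width: 0.0002
  - x0: 0.028
    y0: 0.0
    x1: 0.028
    y1: 0.004
    width: 0.0002
  - x0: 0.0269
    y0: 0.001
    x1: 0.028
    y1: 0.001
    width: 0.0002
  - x0: 0.028
    y0: 0.004
    x1: 0.0301
    y1: 0.004
    width: 0.0002
  - x0: 0.028
    y0: 0.004
    x1: 0.028
    y1: 0.0061
    width: 0.0002
  - x0: 0.032
    y0: 0.0
    x1: 0.032
    y1: 0.004
    width: 0.0002
  - x0: 0.0309
    y0: 0.001
    x1: 0.032
    y1: 0.001
    width: 0.0002
  - x0: 0.032
    y0: 0.004
    x1: 0.0341
    y1: 0.004
    width: 0.0002
  - x0: 0.032
    y0: 0.004
    x1: 0.032
    y1: 0.0061
    width: 0.0002
  prefill:
  - x0: 0.0229
    y0: 0.001
    x1: 0.0239
    y1: 0.001
    width: 0.0002
  - x0: 0.0269
    y0: 0.001
    x1: 0.0279
    y1: 0.001
    width: 0.0002
  - x0: 0.0309
    y0: 0.001
    x1: 0.0319
    y1: 0.001
    width: 0.0002
  ports:
  - name: inlet_cp
    kind: inlet_cp
    center:
    - 0.015
    - 0.0
    normal:
    - -1.0
    - 0.0
    width: 0.0002
    outlet_id: .na.character
  - name: inlet_dp1
    kind: inlet_dp
    center:
    - 0.0229
    - 0.001
    normal:
    - -1.0
    - 0.0
    width: 0.0002
    outlet_id: .na.character
  - name: outlet_a1
    kind: outlet
    center:
    - 0.0261
    - 0.004
    normal:
    - 1.0
    - 0.0
    width: 0.0002
    outlet_id: A
  - name: outlet_b1
    kind: outlet
    center:
    - 0.024
    - 0.0061
    normal:
    - 6.123233995736766e-17
    - 1.0e+00
    width: 0.0002
    outlet_id: B
  - name: inlet_dp2
    kind: inlet_dp
    center:
    - 0.0269
    - 0.001
    normal:
    - -1.0
    - 0.0
    width: 0.0002
    outlet_id: .na.character
  - name: outlet_a2
    kind: outlet
    center:
    - 0.0301
    - 0.004
    normal:
    - 1.0
    - 0.0
    width: 0.0002
    outlet_id: A
  - name: outlet_b2
    kind: outlet
    center:
    - 0.028
    - 0.0061
    normal:
    - 6.123233995736766e-17
    - 1.0e+00
    width: 0.0002
    outlet_id: B
  - name: inlet_dp3
    kind: inlet_dp
    center:
    - 0.0309
    - 0.001
    normal:
    - -1.0
    - 0.0
    width: 0.0002
    outlet_id: .na.character
  - name: outlet_a3
    kind: outlet
    center:
    - 0.0341
    - 0.004
    normal:
    - 1.0
    - 0.0
    width: 0.0002
    outlet_id: A
  - name: outlet_b3
    kind: outlet
    center:
    - 0.032
    - 0.0061
    normal:
    - 6.123233995736766e-17
    - 1.0e+00
    width: 0.0002
    outlet_id: B
  meta:
    junction_radii:
    - 0.024
    - 0.028
    - 0.032
    t_junction_radii:
    - 0.024
    - 0.028
    - 0.032
    sep_offset: 0.004
    t_offset: 0.001
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
  omega_final: 150.0
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
    velocity: 0.025
  dp:
    mode: fixed
    velocity: 0.015
run:
  t_end: 0.02
  snapshot_dt: 0.0005
meta:
  r_eval: 0.032

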