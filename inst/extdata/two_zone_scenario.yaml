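initiation:
  background: 0
  zones:
  - shape: gaussian
    center: 200
    width: 25
    amplitude: 2e-05
    edge_scale: 2
    t_on: 0
    t_off: .inf
  - shape: gaussian
    center: 800
    width: 25
    amplitude: 0.0002
    edge_scale: 2
    t_on: 5000
    t_off: .inf
velocity:
  v_plus: 0.04
  v_minus: 0.04
boundary:
  mode: periodic
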