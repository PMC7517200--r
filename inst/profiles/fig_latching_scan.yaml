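# Single network in the latching regimes used for the pattern-load scan.
kind: single
net:
  'N': 1000
  C_m: 150
  p: 200
  w: 0.8
  tau1: 3.33
  tau2_fast: 100.0
  tau2_slow: 100.0
  gamma2_fast: 1.0
  tau_A: 2
  tau_B: 1000000.0
  gamma_A: 0.0
  S: 5
  a: 0.25
  beta: 11
  U: 0.1
  dynamic_threshold: false
protocol:
  cue_strength: 1.0
  cue_duration: 10
  T_max: 600
  dt: 0.25
  record_dt: 2
  theta_on: 0.5
  theta_off: 0.35
  d_min: 10
  overtake_margin: 0.1
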