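# Cascade input only; no fast inhibition, constant threshold.
kind: pob
pol:
  'N': 600
  C_m: 90
  p: 200
  w: 0.45
  tau1: 3.33
  tau2_fast: 33.3
  tau2_slow: 33.3
  gamma2_fast: 1.0
  tau_A: 2
  tau_B: 1000000.0
  gamma_A: 0.0
  S: 7
  a: 0.25
  beta: 12.5
  U: 0.1
  dynamic_threshold: false
pob:
  'N': 200
  C_m: 150
  p: 200
  w: 0.5
  tau1: 3.33
  tau2_fast: 11.1
  tau2_slow: 33.3
  gamma2_fast: 1.0
  tau_A: 2
  tau_B: 1000000.0
  gamma_A: 0.0
  S: 7
  a: 0.25
  beta: 12.5
  U: 0.1
  dynamic_threshold: false
  threshold_scale: 0.55
  tau_U: 2
coupling:
  C_m_het: 150
  lambda_word: 0.2
  gain: 1.35
  g_cascade:
  - 1.0
  - 0.9
  - 0.8
protocol:
  n_words: 50
  n_batches: 3
  cue_strength: 1.0
  cue_duration: 110
  T_max: 300
  dt: 0.25
  record_dt: 2
  theta_on: 0.5
  theta_off: 0.35
  d_min: 10
  overtake_margin: 0.1
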