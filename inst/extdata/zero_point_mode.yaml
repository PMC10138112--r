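# Single thermostatted harmonic mode sampling zero-point statistics.
model:
  h_s:
    re:
      - [0.0]
  banks:
    phonon:
      omega: [1.0]
      coupling: [0.0]
statmech:
  beta: Inf
  regime: zero_point
  n_samples: 1
  seed: 1
thermostat:
  enabled: true
  mode: zero_point
  chain_length: 2
dynamics:
  solver: nhc
  dt: 0.01
  n_steps: 2000000
  record_every: 2000
output:
  dir: qcldyn-out
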