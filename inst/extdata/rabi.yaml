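# Two-level Rabi benchmark: decoupled subsystem, grid solver.
model:
  h_s:
    re:
      - [0.0, 1.0]
      - [1.0, 0.0]
  chi:
    re:
      - [0.0, 0.0]
      - [0.0, 0.0]
  banks:
    phonon:
      omega: [1.0]
      coupling: [0.0]
statmech:
  beta: 1.0
  regime: thermal_wigner
  n_samples: 1
  seed: 1
  w_s:
    re:
      - [1.0, 0.0]
      - [0.0, 0.0]
dynamics:
  solver: grid
  dt: 0.005
  n_steps: 2000
  record_every: 100
  grid:
    n_r: 48
    n_p: 48
    n_widths: 8
observables:
  - name: sigma_z
    matrix:
      re:
        - [1.0, 0.0]
        - [0.0, -1.0]
output:
  dir: qcldyn-out
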