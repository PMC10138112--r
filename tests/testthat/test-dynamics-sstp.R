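test_that("trajectory solver is bit-deterministic for a fixed seed", {
  H <- spin_boson_symbol()
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1),
                                   thermal = thermal_spec(0.2),
                                   n_samples = 200, seed = 21,
                                   w_s = diag(c(1, 0)) + 0i)
  s1 <- sstp_propagate(ens, H, dt = 0.01, n_steps = 200,
                       hop_mode = "nonadiabatic", seed = 5, record_every = 50)
  s2 <- sstp_propagate(ens, H, dt = 0.01, n_steps = 200,
                       hop_mode = "nonadiabatic", seed = 5, record_every = 50)
  expect_identical(s1$snapshots, s2$snapshots)
  expect_identical(s1$times, s2$times)
})

test_that("pure dephasing has no transitions and constant populations", {
  H <- dephasing_symbol(eps = 1, omega = 1, coupling = 0.3)
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1),
                                   thermal = thermal_spec(1),
                                   n_samples = 400, seed = 22,
                                   w_s = diag(c(1, 0)) + 0i)
  sol <- sstp_propagate(ens, H, dt = 0.02, n_steps = 250,
                        hop_mode = "nonadiabatic", seed = 6, record_every = 50)
  ## chi diagonal in the adiabatic basis: the transition rate vanishes, so
  ## importance weights are untouched (indices may still relabel at the
  ## trivial crossings of the two diagonal surfaces)
  last <- sol$snapshots[[length(sol$snapshots)]]
  expect_true(all(abs(Mod(last$amp) - 1) < 1e-12))
  ser <- qc_average_series(sol, observable_spec(sigma_z))
  ## populations are frozen: the series is constant in time to machine
  ## precision and equals 1 up to Monte-Carlo error
  expect_lt(max(abs(ser$value - ser$value[1])), 1e-10)
  expect_lt(abs(ser$value[1] - 1), 3 * ser$se[1] + 1e-12)
})

test_that("decoupled subsystem reproduces the Rabi oscillation exactly", {
  Om <- 2
  H <- assemble_hamiltonian(subsystem_spec(Om / 2 * sigma_x, chi = 0 * sigma_z),
                            oscillator_bank("phonon", 1, 0))
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1),
                                   thermal = thermal_spec(1),
                                   n_samples = 64, seed = 23,
                                   w_s = diag(c(1, 0)) + 0i)
  sol <- sstp_propagate(ens, H, dt = 0.02, n_steps = 300,
                        hop_mode = "adiabatic_only", seed = 7,
                        record_every = 30)
  ser <- qc_average_series(sol, observable_spec(sigma_z))
  expect_lt(max(abs(ser$value - cos(Om * ser$time))), 1e-10)
})

test_that("dephasing coherence matches the quantized-mode oracle", {
  eps <- 1; om <- 1; C <- 0.3; beta <- 1
  H <- dephasing_symbol(eps, om, C)
  wplus <- matrix(0.5, 2, 2) + 0i
  ens <- sample_initial_conditions(oscillator_bank("phonon", om),
                                   thermal = thermal_spec(beta),
                                   n_samples = 20000, seed = 24, w_s = wplus)
  sol <- sstp_propagate(ens, H, dt = 0.02, n_steps = 250,
                        hop_mode = "nonadiabatic", seed = 8, record_every = 50)
  ser <- qc_average_series(sol, observable_spec(sigma_x))
  oracle <- fock_dephasing_oracle(eps, om, C, beta, wplus)
  for (k in 2:length(ser$time)) {
    exact <- 2 * Re(oracle(ser$time[k]))
    expect_lt(abs(ser$value[k] - exact), 3.5 * ser$se[k] + 1e-3)
  }
})

test_that("runaway weights are frozen and flagged", {
  H <- spin_boson_symbol(Omega = 0.8, omega = 1, coupling = 0.4)
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1),
                                   thermal = thermal_spec(0.1),
                                   n_samples = 500, seed = 25,
                                   w_s = diag(c(1, 0)) + 0i)
  sol <- sstp_propagate(ens, H, dt = 0.02, n_steps = 600,
                        hop_mode = "nonadiabatic", seed = 9,
                        record_every = 600, weight_cutoff = 3)
  expect_gt(sol$n_frozen, 0)
  last <- sol$snapshots[[length(sol$snapshots)]]
  expect_true(all(is.finite(Mod(last$amp))))
})
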