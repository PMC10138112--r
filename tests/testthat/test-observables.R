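decoupled_solution <- function(Omega = 1.5, w_s, n_samples = 64, n_steps = 400,
                               dt = 0.02, seed = 31) {
  H <- assemble_hamiltonian(subsystem_spec(Omega / 2 * sigma_z, chi = 0 * sigma_z),
                            oscillator_bank("phonon", 1, 0))
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1),
                                   thermal = thermal_spec(1),
                                   n_samples = n_samples, seed = seed, w_s = w_s)
  sstp_propagate(ens, H, dt = dt, n_steps = n_steps,
                 hop_mode = "adiabatic_only", seed = seed + 1,
                 record_every = 40)
}

test_that("averages of the identity and of sigma_z at t = 0 are exact", {
  H <- spin_boson_symbol()
  W <- initial_grid_state(H, thermal_spec(1), w_s = diag(c(1, 0)) + 0i,
                          n_r = 48, n_p = 48)
  expect_equal(qc_average(W, observable_spec(diag(2))), 1, tolerance = 1e-8)
  expect_equal(qc_average(W, observable_spec(sigma_z)), 1, tolerance = 1e-8)
  sol <- decoupled_solution(w_s = diag(c(1, 0)) + 0i)
  a0 <- qc_average(sol, observable_spec(diag(2)), t = 0)
  expect_equal(a0$value, 1, tolerance = 1e-12)
  az <- qc_average(sol, observable_spec(sigma_z), t = 0)
  expect_equal(az$value, 1, tolerance = 1e-12)
})

test_that("unnormalized grid states are rejected with the measured norm", {
  H <- spin_boson_symbol()
  W <- initial_grid_state(H, thermal_spec(1), n_r = 48, n_p = 48)
  W$rho <- 2 * W$rho
  expect_error(qc_average(W, observable_spec(sigma_z)), "not normalized")
})

test_that("equal-time autocorrelation of sigma_z is exactly one", {
  sol <- decoupled_solution(w_s = diag(c(1, 0)) + 0i)
  cc <- qc_correlation(sol, observable_spec(sigma_z), observable_spec(sigma_z),
                       times = 0)
  expect_equal(cc$re, 1, tolerance = 1e-12)
  expect_equal(cc$im, 0, tolerance = 1e-12)
})

test_that("decoupled sigma_x autocorrelation oscillates at the Bohr frequency", {
  Om <- 1.5
  sol <- decoupled_solution(Omega = Om, w_s = diag(c(0.5, 0.5)) + 0i)
  cc <- qc_correlation(sol, observable_spec(sigma_x), observable_spec(sigma_x))
  ## <sigma_x(t) sigma_x> for the maximally mixed state: cos(Om t) + 0i
  ## (the imaginary parts of the two coherence branches cancel)
  expect_lt(max(abs(cc$re - cos(Om * cc$time))), 1e-10)
  expect_lt(max(abs(cc$im)), 1e-10)
})

test_that("classical-only correlation functions are real", {
  H <- assemble_hamiltonian(subsystem_spec(0 * sigma_z, chi = 0 * sigma_z),
                            oscillator_bank("phonon", 1.3, 0))
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1.3),
                                   thermal = thermal_spec(1),
                                   n_samples = 500, seed = 33,
                                   w_s = diag(c(1, 0)) + 0i)
  sol <- sstp_propagate(ens, H, dt = 0.02, n_steps = 200,
                        hop_mode = "adiabatic_only", seed = 34,
                        record_every = 50)
  obs_r <- observable_spec(matrix(0, 2, 2),
                           classical_part = function(r, p) r[, 1])
  cc <- qc_correlation(sol, obs_r, obs_r)
  expect_lt(max(abs(cc$im)), 1e-10)
  ## <R(t) R(0)> of a thermal harmonic mode: var_r cos(omega t)
  vr <- wigner_thermal_moments(1, 1.3)$var_r
  expect_lt(max(abs(cc$re / (vr * cos(1.3 * cc$time)) - 1)), 0.3)
})

test_that("ensemble averages converge to the grid value as N grows", {
  eps <- 1; om <- 1; C <- 0.3
  H <- dephasing_symbol(eps, om, C)
  wplus <- matrix(0.5, 2, 2) + 0i
  Wg <- initial_grid_state(H, thermal_spec(1), w_s = wplus, n_r = 96, n_p = 96)
  Wg <- propagate_grid(Wg, H, 0.01, 200, picture = "schrodinger")
  ref <- qc_average(Wg, observable_spec(sigma_x))
  errs <- vapply(c(400, 1600, 6400), function(N) {
    e <- vapply(1:4, function(rep) {
      ens <- sample_initial_conditions(oscillator_bank("phonon", om),
                                       thermal = thermal_spec(1),
                                       n_samples = N, seed = 100 * rep + N,
                                       w_s = wplus)
      sol <- sstp_propagate(ens, H, dt = 0.02, n_steps = 100,
                            hop_mode = "nonadiabatic", seed = rep,
                            record_every = 100)
      abs(qc_average(sol, observable_spec(sigma_x), t = 2)$value - ref)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(c(400, 1600, 6400))))[2]
  expect_lt(slope, -0.2)
  expect_gt(slope, -0.9)
})

test_that("correlation functions satisfy C(-t) = Conj(C(t)) on a reversible benchmark", {
  ## decoupled subsystem, maximally mixed state: C(t) = cos(Om t); evolve the
  ## observable forward (Heisenberg) and backward (opposite sign) on the grid
  Om <- 1.2
  H <- assemble_hamiltonian(subsystem_spec(Om / 2 * sigma_z, chi = 0 * sigma_z),
                            oscillator_bank("phonon", 1, 0))
  w0 <- diag(c(0.5, 0.5)) + 0i
  W <- initial_grid_state(H, thermal_spec(1), w_s = w0, n_r = 48, n_p = 48,
                          n_widths = 8)
  O <- uniform_grid_observable(W, sigma_x)
  corr_at <- function(picture) {
    Ot <- propagate_grid(O, H, 0.005, 100, picture = picture)
    ## Tr' int W O1(+-t) O2 with O2 = sigma_x at t = 0
    hr <- diff(W$r_grid[1:2]); hp <- diff(W$p_grid[1:2])
    acc <- 0
    for (a in 1:2) for (b in 1:2) for (cc in 1:2)
      acc <- acc + sum(W$rho[a, b, , ] * Ot$rho[b, cc, , ]) * sigma_x[cc, a]
    acc * hr * hp
  }
  cpos <- corr_at("heisenberg")     # C(+t)
  cneg <- corr_at("schrodinger")    # C(-t): opposite generator sign
  expect_equal(cneg, Conj(cpos), tolerance = 1e-6)
  expect_equal(Re(cpos), cos(Om * 0.5), tolerance = 1e-6)
})

test_that("response spectra locate known peaks within one frequency bin", {
  tg <- seq(0, 2 * pi * 50, length.out = 4096)
  sp <- response_spectrum(cos(tg), tg)
  expect_lt(abs(abs(sp$peak_omega) - 1), sp$domega)
  sp0 <- response_spectrum(rep(0 + 0i, 256), seq(0, 255) * 0.1)
  expect_equal(max(sp0$power), 0)
  expect_error(response_spectrum(1:10, cumsum(runif(10))), "uniform")
  ## correlation of a decoupled two-level system peaks at the adiabatic gap
  Om <- 1.5
  sol <- decoupled_solution(Omega = Om, w_s = diag(c(0.5, 0.5)) + 0i,
                            n_steps = 2048, dt = 0.05, n_samples = 16)
  solc <- sstp_propagate(
    sample_initial_conditions(oscillator_bank("phonon", 1),
                              thermal = thermal_spec(1), n_samples = 16,
                              seed = 35, w_s = diag(c(0.5, 0.5)) + 0i),
    assemble_hamiltonian(subsystem_spec(Om / 2 * sigma_z, chi = 0 * sigma_z),
                         oscillator_bank("phonon", 1, 0)),
    dt = 0.05, n_steps = 2048, hop_mode = "adiabatic_only", seed = 36,
    record_every = 1)
  cc <- qc_correlation(solc, observable_spec(sigma_x), observable_spec(sigma_x))
  sp2 <- response_spectrum(cc, cc$time)
  H <- assemble_hamiltonian(subsystem_spec(Om / 2 * sigma_z, chi = 0 * sigma_z),
                            oscillator_bank("phonon", 1, 0))
  gap <- diff(adiabatic_eigensystem(H, phase_point(0, 0))$energies)
  expect_lt(abs(abs(sp2$peak_omega) - gap), sp2$domega)
})
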