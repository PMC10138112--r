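one_mode_symbol <- function(omega = 1, coupling = 0) {
  assemble_hamiltonian(subsystem_spec(matrix(0)),
                       oscillator_bank("phonon", omega, coupling))
}

test_that("extended energy reproduces hand-evaluated cases and is linear in eta", {
  H <- one_mode_symbol()
  nhc <- nhc_spec(1, targets = 1, masses = 1)
  ext <- extended_point(phase_point(0, 1))
  e <- extended_energy(ext, H, nhc)
  expect_equal(e$scalar, 0.5)
  ## everything at rest, no coupling: scalar 0, matrix h_s
  hs <- random_hermitian(2, 3)
  H2 <- assemble_hamiltonian(subsystem_spec(hs, chi = random_hermitian(2, 4)),
                             oscillator_bank("phonon", 1, 0))
  e2 <- extended_energy(extended_point(phase_point(0, 0)), H2, nhc)
  expect_equal(e2$scalar, 0)
  expect_equal(e2$matrix, hs)
  ## shifting eta_1 of mode 1 by Delta adds exactly T(1) * Delta
  nhc3 <- nhc_spec(1, targets = 0.7, masses = 1)
  base <- extended_energy(ext, H, nhc3)$scalar
  ext2 <- extended_point(phase_point(0, 1), eta = matrix(c(1.5, 0), 1, 2))
  expect_equal(extended_energy(ext2, H, nhc3)$scalar - base, 0.7 * 1.5)
})

test_that("NHC structure matrix is exactly antisymmetric and symplectic at rest", {
  set.seed(11)
  nhc <- nhc_spec(2, targets = c(1, 0.5), chain_length = 2,
                  masses = matrix(runif(4, 0.5, 2), 2, 2))
  ext <- extended_point(phase_point(rnorm(2), rnorm(2)),
                        eta = matrix(rnorm(4), 2, 2),
                        p_eta = matrix(rnorm(4), 2, 2))
  B <- nhc_structure_matrix(ext, nhc)
  expect_identical(B, -t(B))
  ## with all momenta at rest the matrix is the block-symplectic pattern
  ext0 <- extended_point(phase_point(rnorm(2), c(0, 0)),
                         eta = matrix(rnorm(4), 2, 2),
                         p_eta = matrix(0, 2, 2))
  B0 <- nhc_structure_matrix(ext0, nhc)
  half <- nrow(B0) / 2
  expect_equal(B0, rbind(cbind(matrix(0, half, half), diag(half)),
                         cbind(-diag(half), matrix(0, half, half))))
})

test_that("structure matrix times the energy gradient gives the equations of motion", {
  set.seed(12)
  for (rep in 1:3) {
    nhc <- nhc_spec(2, targets = runif(2, 0.5, 2), chain_length = 3,
                    masses = matrix(runif(6, 0.5, 2), 2, 3))
    ext <- extended_point(phase_point(rnorm(2), rnorm(2)),
                          eta = matrix(rnorm(6), 2, 3),
                          p_eta = matrix(rnorm(6), 2, 3))
    sf <- rnorm(2)
    B <- nhc_structure_matrix(ext, nhc)
    g <- qcldyn:::ext_gradient(ext, NULL, nhc, sf)
    lhs <- as.numeric(B %*% g)
    eom <- extended_eom(ext, nhc = nhc, surface_force = sf)
    lay <- qcldyn:::ext_layout(nhc)
    rhs <- numeric(lay$dim)
    rhs[lay$i_r] <- eom$r
    rhs[lay$i_p] <- eom$p
    for (I in 1:2) for (L in 1:3) {
      rhs[lay$i_eta(I, L)] <- eom$eta[I, L]
      rhs[lay$i_peta(I, L)] <- eom$p_eta[I, L]
    }
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("equations of motion match hand-substituted values", {
  nhc <- nhc_spec(1, targets = 1, masses = 1)
  ## R=0, P=1, omega=1, T=1, M=1, chains at rest
  ext <- extended_point(phase_point(0, 1))
  d <- extended_eom(ext, nhc = nhc, surface_force = 0)   # F = -omega^2 R = 0
  expect_equal(d$r, 1)
  expect_equal(d$p, 0)
  expect_equal(as.numeric(d$eta), c(0, 0))
  expect_equal(as.numeric(d$p_eta), c(0, -1))
  ## thermostat equilibrium: P^2 = T and chains at rest -> Pdot_eta1 = 0
  extq <- extended_point(phase_point(0.3, sqrt(nhc$targets)))
  dq <- extended_eom(extq, nhc = nhc, surface_force = -0.3)
  expect_equal(dq$p_eta[1, 1], 0)
})

test_that("conserved extended energy: tiny drift with and without thermostats", {
  H <- one_mode_symbol()
  th <- thermal_spec(1)
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1), thermal = th,
                                   n_samples = 1, seed = 5)
  bare <- integrate_nhc(ens, H, NULL, dt = 1e-3, n_steps = 1e5)
  expect_lt(max(bare$record$drift), 1e-8)
  nhc <- nhc_spec_for(H, th)
  thermo <- integrate_nhc(ens, H, nhc, dt = 1e-3, n_steps = 1e5)
  expect_lt(max(thermo$record$drift), 1e-6)
})

test_that("unthermostatted zero-coupling motion is plain harmonic", {
  H <- one_mode_symbol(omega = 1.7)
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1.7),
                                   thermal = thermal_spec(1),
                                   n_samples = 1, seed = 6)
  r0 <- ens$r[1, 1]; p0 <- ens$p[1, 1]
  out <- integrate_nhc(ens, H, NULL, dt = 0.01, n_steps = 250)
  t <- 2.5; w <- 1.7
  expect_equal(out$r[1, 1], r0 * cos(w * t) + p0 / w * sin(w * t),
               tolerance = 1e-9)
  expect_equal(out$p[1, 1], p0 * cos(w * t) - w * r0 * sin(w * t),
               tolerance = 1e-9)
})

test_that("thermostatted trajectories sample the target Gaussian (KS, alpha = 0.01)", {
  H <- one_mode_symbol()
  th <- thermal_spec(1)
  T_target <- 1 / effective_beta(1, 1)
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1), thermal = th,
                                   n_samples = 1, seed = 9)
  nhc <- nhc_spec_for(H, th)
  out <- integrate_nhc(ens, H, nhc, dt = 0.01, n_steps = 4e5,
                       record_every = 200)
  r <- out$record$r[, 1, 1]; p <- out$record$p[, 1, 1]
  expect_gt(ks.test(p, "pnorm", sd = sqrt(T_target))$p.value, 0.01)
  expect_gt(ks.test(r, "pnorm", sd = sqrt(T_target))$p.value, 0.01)
})

test_that("an unstable time step trips the chain-momentum overflow guard", {
  H <- one_mode_symbol()
  ens <- sample_initial_conditions(oscillator_bank("phonon", 1),
                                   thermal = thermal_spec(1),
                                   n_samples = 1, seed = 10)
  nhc <- nhc_spec(1, targets = 1, masses = 1e-8)
  expect_error(integrate_nhc(ens, H, nhc, dt = 5, n_steps = 2000),
               "overflow guard")
})
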