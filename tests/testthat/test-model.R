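test_that("assembled symbol evaluates to the hand-computed matrix", {
  sub <- subsystem_spec(diag(c(1, -1)), chi = diag(c(1, -1)))
  H <- assemble_hamiltonian(sub, oscillator_bank("phonon", 1, 0.3))
  m <- H$evaluate(phase_point(1, 0))
  expect_equal(m, diag(c(1.2, -0.2)) + 0i, tolerance = 1e-12)
})

test_that("all couplings zero reproduces h_s at the phase-space origin", {
  hs <- random_hermitian(3, 1)
  sub <- subsystem_spec(hs, chi = random_hermitian(3, 2))
  H <- assemble_hamiltonian(sub, oscillator_bank("phonon", c(1, 2), c(0, 0)))
  expect_equal(H$evaluate(phase_point(c(0, 0), c(0, 0))), hs)
})

test_that("symbols are Hermitian with real spectra and the classical part is scalar", {
  for (seed in 1:5) {
    set.seed(seed)
    hs <- random_hermitian(2, seed + 10)
    sub <- subsystem_spec(hs, chi = random_hermitian(2, seed + 20),
                          zeta = random_hermitian(2, seed + 30))
    H <- assemble_hamiltonian(sub,
                              oscillator_bank("phonon", runif(2, 0.5, 2), rnorm(2)),
                              oscillator_bank("em", runif(1, 0.5, 2), rnorm(1)))
    pt <- phase_point(rnorm(3), rnorm(3))
    m <- H$evaluate(pt)
    expect_lt(max(abs(m - Conj(t(m)))), 1e-12)
    ev <- eigen(m, only.values = TRUE)$values
    expect_lt(max(abs(Im(ev))), 1e-12)
    ## trace identity: classical energy enters proportional to the identity
    ecl <- sum(pt$p^2) / 2 + sum(H$omega^2 * pt$r^2) / 2
    coup <- sum(vapply(seq_along(H$omega), function(j)
      H$coupling[j] * pt$r[j] *
        Re(sum(diag(list(sub$chi, sub$zeta)[[H$which_op[j]]]))), numeric(1)))
    expect_equal(Re(sum(diag(m))), Re(sum(diag(hs))) + 2 * ecl - coup,
                 tolerance = 1e-10)
  }
})

test_that("subsystem and bank invariants are enforced", {
  expect_error(subsystem_spec(matrix(c(0, 1, 0, 0), 2, 2)), "Hermitian")
  expect_error(subsystem_spec(diag(2), chi = diag(3)), "must be 2 x 2")
  expect_error(oscillator_bank("phonon", c(1, -1)), "phonon")
  expect_error(oscillator_bank("em", 1, c(0.1, 0.2)), "em")
  sub <- subsystem_spec(diag(2))
  bank_em <- oscillator_bank("em", 1)
  expect_error(assemble_hamiltonian(sub, phonons = bank_em), "phonon")
})

test_that("classical force matches hand differentiation and finite differences", {
  sub <- subsystem_spec(diag(c(1, -1)), chi = diag(c(1, -1)))
  ## decoupled mode omega = 2 at R = 0.5: force = -omega^2 R Id = -2 Id
  H0 <- assemble_hamiltonian(sub, oscillator_bank("phonon", 2, 0))
  f <- classical_force(H0, phase_point(0.5, 0))
  expect_equal(f[[1]], -2 * diag(2) + 0i, tolerance = 1e-12)
  ## at R = 0 with C = 0.3, chi = sigma_z: force = 0.3 sigma_z
  H1 <- assemble_hamiltonian(sub, oscillator_bank("phonon", 2, 0.3))
  f1 <- classical_force(H1, phase_point(0, 0))
  expect_equal(f1[[1]], 0.3 * diag(c(1, -1)) + 0i, tolerance = 1e-12)
  ## finite differences of evaluate agree with the closed-form gradients
  set.seed(4)
  sub2 <- subsystem_spec(random_hermitian(2, 5), chi = random_hermitian(2, 6),
                         zeta = random_hermitian(2, 7))
  H2 <- assemble_hamiltonian(sub2, oscillator_bank("phonon", 1.3, 0.4),
                             oscillator_bank("em", 0.7, -0.2))
  pt <- phase_point(rnorm(2), rnorm(2))
  gr <- H2$gradient_r(pt); gp <- H2$gradient_p(pt)
  fr <- qcldyn:::fd_gradient(H2, pt, "r", h = 1e-4)
  fp <- qcldyn:::fd_gradient(H2, pt, "p", h = 1e-4)
  for (j in 1:2) {
    expect_lt(max(abs(gr[[j]] - fr[[j]])), 1e-6)
    expect_lt(max(abs(gp[[j]] - fp[[j]])), 1e-6)
  }
  expect_error(classical_force(H2, phase_point(1, 1)), "modes")
})

test_that("adiabatic eigensystem is ordered, unitary and phase-deterministic", {
  sub <- subsystem_spec(diag(c(1, -1)), chi = diag(c(1, -1)))
  H <- assemble_hamiltonian(sub, oscillator_bank("phonon", 1, 0.3))
  es <- adiabatic_eigensystem(H, phase_point(1, 0))
  expect_equal(es$energies, c(-0.2, 1.2), tolerance = 1e-12)
  ## h_s = (Omega/2) sigma_x with Omega = 2: energies -1, 1 (plus classical)
  sub2 <- subsystem_spec(sigma_x)
  H2 <- assemble_hamiltonian(sub2, oscillator_bank("phonon", 1, 0))
  es2 <- adiabatic_eigensystem(H2, phase_point(0, 0))
  expect_equal(es2$energies, c(-1, 1), tolerance = 1e-12)
  ## random symbol: basis diagonalizes, columns orthonormal, phase fixed
  sub3 <- subsystem_spec(random_hermitian(3, 8), chi = random_hermitian(3, 9))
  H3 <- assemble_hamiltonian(sub3, oscillator_bank("phonon", 1.1, 0.5))
  pt <- phase_point(0.7, -0.3)
  es3 <- adiabatic_eigensystem(H3, pt)
  d <- Conj(t(es3$basis)) %*% H3$evaluate(pt) %*% es3$basis
  expect_lt(max(abs(d - diag(es3$energies))), 1e-12)
  expect_lt(max(abs(Conj(t(es3$basis)) %*% es3$basis - diag(3))), 1e-12)
  for (k in 1:3) {
    v <- es3$basis[, k]; i <- which.max(abs(v))
    expect_gt(Re(v[i]), 0); expect_lt(abs(Im(v[i])), 1e-12)
  }
  expect_false(es3$near_degenerate)
  ## exact degeneracy is flagged
  sub4 <- subsystem_spec(diag(2))
  H4 <- assemble_hamiltonian(sub4, oscillator_bank("phonon", 1, 0))
  expect_true(adiabatic_eigensystem(H4, phase_point(0, 0))$near_degenerate)
})

test_that("bracket structure matrices are exactly antisymmetric", {
  expect_identical(omega_matrix(), -t(omega_matrix()))
  for (nm in c(1, 3)) {
    L <- lambda_matrix(nm)
    expect_identical(L, -t(L))
    expect_equal(L %*% L, -diag(2 * nm))
  }
})
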