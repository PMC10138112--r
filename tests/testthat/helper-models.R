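## Shared fixtures: Pauli matrices, canonical small models, quadrature helpers.

sigma_x <- matrix(c(0, 1, 1, 0), 2, 2)
sigma_y <- matrix(c(0, 1i, -1i, 0), 2, 2)
sigma_z <- diag(c(1, -1))

## two-level subsystem h_s = (Omega/2) sigma_x coupled through chi = sigma_z
## to a single phonon mode: the canonical spin-boson testbed
spin_boson_symbol <- function(Omega = 0.8, omega = 1, coupling = 0.1) {
  sub <- subsystem_spec(Omega / 2 * sigma_x, chi = sigma_z)
  assemble_hamiltonian(sub, oscillator_bank("phonon", omega, coupling))
}

## pure dephasing: h_s and chi both diagonal
dephasing_symbol <- function(eps = 1, omega = 1, coupling = 0.3) {
  sub <- subsystem_spec(eps / 2 * sigma_z, chi = sigma_z)
  assemble_hamiltonian(sub, oscillator_bank("phonon", omega, coupling))
}

## random Hermitian matrix
random_hermitian <- function(n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n) + 1i * matrix(rnorm(n * n), n, n)
  (m + Conj(t(m))) / 2
}

## trace of Tr(W O) quadrature for two grid states on the same lattice
grid_overlap <- function(wstate, ostate) {
  hr <- diff(wstate$r_grid[1:2]); hp <- diff(wstate$p_grid[1:2])
  n <- wstate$n
  acc <- 0
  for (a in seq_len(n)) for (b in seq_len(n))
    acc <- acc + sum(wstate$rho[a, b, , ] * ostate$rho[b, a, , ])
  acc * hr * hp
}

## energy functional Tr' int W Htilde over a grid state
grid_energy_functional <- function(state, symbol) {
  parts <- list(h0 = symbol$sub$h_s,
                op = if (symbol$which_op[1] == 1) symbol$sub$chi else symbol$sub$zeta,
                omega = symbol$omega[1], coupling = symbol$coupling[1])
  hr <- diff(state$r_grid[1:2]); hp <- diff(state$p_grid[1:2])
  acc <- 0
  for (ir in seq_along(state$r_grid)) {
    R <- state$r_grid[ir]
    hmat <- parts$h0 - parts$coupling * R * parts$op
    for (ip in seq_along(state$p_grid)) {
      P <- state$p_grid[ip]
      ecl <- P^2 / 2 + parts$omega^2 * R^2 / 2
      acc <- acc + sum(diag((hmat + ecl * diag(2)) %*% state$rho[, , ir, ip]))
    }
  }
  Re(acc) * hr * hp
}
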