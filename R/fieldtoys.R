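## Exactly solvable companion models: Bohr-frequency/superposition-lifetime
## utilities, and a thermo-field "doubled boson" mode on a truncated Fock
## space.  Each physical mode (annihilator a) is paired with a fictitious
## double (v); the pair Hamiltonian
##   H = omega (a+a - v+v) + i gamma (a+v+ - a v)
## generates two-mode squeezing: from the vacuum, <a+a>(t) = sinh^2(gamma t).

#' Bohr frequency of two energy eigenvalues
#'
#' `omega = (E_upper - E_lower) / hbar` with `hbar = 1`.
#'
#' @param e_upper,e_lower Energies.
#' @return Frequency (vectorized).
#' @export
bohr_frequency <- function(e_upper, e_lower) {
  (e_upper - e_lower)
}

#' Lifetime of a superposition with energy gap `delta_e`
#'
#' `tau = h / Delta E = 2 pi / Delta E` in `hbar = 1` units, so that
#' `bohr_frequency * tau = 2 pi` for the same gap.
#'
#' @param delta_e Positive energy gap (vectorized).
#' @return Lifetime.
#' @export
or_lifetime <- function(delta_e) {
  delta_e <- as.numeric(delta_e)
  if (any(!is.finite(delta_e)) || any(delta_e <= 0))
    stop("'delta_e' must be positive and finite")
  2 * pi / delta_e
}

#' Doubled-boson mode specification
#'
#' @param omega Mode frequency.
#' @param gamma Damping constant (>= 0); couples the mode to its double.
#' @param cutoff Fock truncation per sector (>= 2).
#' @return Object of class `qcl_dqmb`.
#' @export
dqmb_mode_spec <- function(omega, gamma, cutoff = 40L) {
  cutoff <- as.integer(cutoff)
  if (cutoff < 2) stop("'cutoff' must be >= 2")
  if (gamma < 0) stop("'gamma' must be >= 0")
  if (!is.finite(omega)) stop("'omega' must be finite")
  structure(list(omega = omega, gamma = gamma, cutoff = cutoff),
            class = "qcl_dqmb")
}

## Truncated annihilation operator on cutoff Fock levels (0 .. cutoff-1).
ladder_operator <- function(cutoff) {
  a <- matrix(0, cutoff, cutoff)
  if (cutoff > 1) a[cbind(seq_len(cutoff - 1), 2:cutoff)] <- sqrt(seq_len(cutoff - 1))
  a
}

#' Doubled-boson pair Hamiltonian on the truncated two-sector Fock space
#'
#' `H = omega (a+a (x) Id - Id (x) v+v) + i gamma (a+ (x) v+ - a (x) v)`,
#' basis `|n_a> (x) |n_v>` with `n = 0 .. cutoff-1` per sector (physical
#' sector first in the Kronecker ordering).
#'
#' @param spec A [dqmb_mode_spec()].
#' @return Hermitian complex matrix of side `cutoff^2`.
#' @export
dqmb_hamiltonian <- function(spec) {
  stopifnot(inherits(spec, "qcl_dqmb"))
  nc <- spec$cutoff
  a <- ladder_operator(nc)
  num <- t(a) %*% a
  id <- diag(nc)
  h0 <- spec$omega * (kronecker(num, id) - kronecker(id, num))
  hi <- 1i * spec$gamma * (kronecker(t(a), t(a)) - kronecker(a, a))
  h <- h0 + hi
  storage.mode(h) <- "complex"
  h
}

## Restriction of H to the invariant zero-charge sector span{|n, n>}: the
## charge a+a - v+v commutes with H (truncation preserves the block
## structure), and vacuum evolution never leaves the sector.  Tridiagonal:
## <n+1, n+1| H |n, n> = i gamma (n + 1), diagonal zero.
dqmb_sector_hamiltonian <- function(spec) {
  nc <- spec$cutoff
  h <- matrix(0 + 0i, nc, nc)
  up <- 1i * spec$gamma * seq_len(nc - 1)
  h[cbind(2:nc, seq_len(nc - 1))] <- up
  h[cbind(seq_len(nc - 1), 2:nc)] <- Conj(up)
  h
}

#' Physical-mode occupation of the vacuum-evolved doubled-boson pair
#'
#' Evolves the two-sector vacuum under [dqmb_hamiltonian()] and returns
#' `<a+a>(t)`.  By conservation of the charge `a+a - v+v` the vacuum state
#' stays in the pair sector `|n, n>`, so the propagation is done exactly in
#' that sector.  The truncation is monitored: if the population leaked into
#' the top Fock levels exceeds `leak_tol`, the call is rejected with a
#' suggested larger cutoff.
#'
#' @param spec A [dqmb_mode_spec()].
#' @param t Time(s), scalar or vector.
#' @param leak_tol Maximum tolerated population in the top two levels
#'   (default `1e-8`).
#' @return Numeric vector `<a+a>(t)`; attribute `"leakage"` carries the
#'   worst-case top-level population.
#' @export
dqmb_mode_occupation <- function(spec, t, leak_tol = 1e-8) {
  stopifnot(inherits(spec, "qcl_dqmb"))
  t <- as.numeric(t)
  nc <- spec$cutoff
  h <- dqmb_sector_hamiltonian(spec)
  es <- eigen(h, symmetric = TRUE)
  psi0 <- c(1, rep(0, nc - 1))
  amp0 <- Conj(t(es$vectors)) %*% psi0
  nvec <- seq_len(nc) - 1
  occ <- numeric(length(t))
  leak <- 0
  for (k in seq_along(t)) {
    psi <- es$vectors %*% (exp(-1i * es$values * t[k]) * amp0)
    prob <- Mod(psi)^2
    occ[k] <- sum(nvec * prob)
    leak <- max(leak, sum(prob[(nc - 1):nc]))
  }
  if (leak > leak_tol) {
    r <- spec$gamma * max(abs(t))
    lam <- tanh(r)^2
    sugg <- if (lam > 0 && lam < 1)
      ceiling(log(leak_tol * (1 - lam)) / log(lam)) + 5 else 2 * nc
    stop(sprintf(paste0("truncation leakage %.3g exceeds %g at cutoff %d; ",
                        "suggested cutoff >= %d"),
                 leak, leak_tol, nc, max(sugg, 2 * nc)))
  }
  attr(occ, "leakage") <- leak
  occ
}

#' Expectation trajectory of the doubled-boson charge and occupations
#'
#' Full-space evolution of an initial state under [dqmb_hamiltonian()],
#' returning `<a+a>`, `<v+v>` and the conserved charge `<a+a - v+v>` on a
#' time grid.  Intended for invariant checks at modest cutoffs.
#'
#' @param spec A [dqmb_mode_spec()].
#' @param t Time vector.
#' @param psi0 Initial state vector of length `cutoff^2`; default the
#'   two-sector vacuum.
#' @return Data frame with columns `time`, `n_a`, `n_v`, `charge`.
#' @export
dqmb_expectations <- function(spec, t, psi0 = NULL) {
  stopifnot(inherits(spec, "qcl_dqmb"))
  nc <- spec$cutoff
  dim_full <- nc * nc
  if (is.null(psi0)) psi0 <- c(1, rep(0 + 0i, dim_full - 1))
  if (length(psi0) != dim_full) stop("'psi0' has the wrong length")
  psi0 <- psi0 / sqrt(sum(Mod(psi0)^2))
  h <- dqmb_hamiltonian(spec)
  es <- eigen(h, symmetric = TRUE)
  amp0 <- Conj(t(es$vectors)) %*% psi0
  nvec <- seq_len(nc) - 1
  na_diag <- rep(nvec, each = nc)     # kronecker(num, id) diagonal
  nv_diag <- rep(nvec, times = nc)
  out <- lapply(t, function(tk) {
    psi <- es$vectors %*% (exp(-1i * es$values * tk) * amp0)
    prob <- Mod(psi)^2
    c(sum(na_diag * prob), sum(nv_diag * prob))
  })
  out <- do.call(rbind, out)
  data.frame(time = t, n_a = out[, 1], n_v = out[, 2],
             charge = out[, 1] - out[, 2])
}
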