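## Per-mode Nose-Hoover chain (NHC) thermostats in extended phase space.
##
## Each classical mode I carries a chain of auxiliary variables
## (eta_L^(I), P_etaL^(I)), L = 1..chain_length, with inertial parameters
## M_etaL and target temperature T(I).  The extended equations of motion for a
## chain of length 2 are
##   Rdot = P
##   Pdot = F - P P_eta1 / M_eta1
##   etadot_L = P_etaL / M_etaL
##   Pdot_eta1 = P^2 - T(I) - P_eta1 P_eta2 / M_eta2
##   Pdot_eta2 = P_eta1^2 / M_eta1 - T(I)
## (k_B = 1, unit mode mass); they follow from the antisymmetric structure
## matrix applied to the gradient of the extended energy
##   H_e = H(X) + sum_{I,L} P_etaL^2 / (2 M_etaL) + sum_{I,L} T(I) eta_L,
## which is therefore exactly conserved along the flow.

#' Nose-Hoover chain settings
#'
#' @param n_modes Number of thermostatted modes.
#' @param targets Per-mode target temperature `T(I) > 0` (`k_B = 1`); recycled.
#'   Use [effective_beta()] to build zero-point-preserving targets
#'   `T(I) = 1/beta(I)`.
#' @param chain_length Links per chain (default 2).
#' @param masses Inertial parameters `M_etaL`, an `n_modes x chain_length`
#'   matrix or a value recycled to it.  Default `NULL`: set to
#'   `T(I) / omega_ref^2` with `omega_ref = 1` (a relaxation time of one
#'   inverse frequency unit); pass explicit masses for stiff modes.
#' @return Object of class `qcl_nhc`.
#' @export
nhc_spec <- function(n_modes, targets, chain_length = 2L, masses = NULL) {
  n_modes <- as.integer(n_modes)
  chain_length <- as.integer(chain_length)
  if (chain_length < 1) stop("'chain_length' must be >= 1")
  targets <- rep_len(as.numeric(targets), n_modes)
  if (any(targets <= 0)) stop("all thermostat targets must be positive")
  if (is.null(masses)) masses <- matrix(targets, n_modes, chain_length)
  if (is.null(dim(masses)))
    masses <- matrix(rep_len(as.numeric(masses), n_modes * chain_length),
                     n_modes, chain_length)
  if (any(masses <= 0)) stop("all NHC inertial parameters must be positive")
  structure(list(n_modes = n_modes, chain_length = chain_length,
                 masses = masses, targets = targets),
            class = "qcl_nhc")
}

#' Extended phase-space point
#'
#' Physical phase point plus the per-mode chain variables.
#'
#' @param point A [phase_point()].
#' @param eta,p_eta `n_modes x chain_length` matrices of chain coordinates and
#'   momenta; default zero.
#' @param chain_length Used when `eta`/`p_eta` are omitted.
#' @return Object of class `qcl_extended_point`.
#' @export
extended_point <- function(point, eta = NULL, p_eta = NULL, chain_length = 2L) {
  stopifnot(inherits(point, "qcl_phase_point"))
  nm <- length(point$r)
  if (is.null(eta)) eta <- matrix(0, nm, chain_length)
  if (is.null(p_eta)) p_eta <- matrix(0, nm, chain_length)
  eta <- as.matrix(eta); p_eta <- as.matrix(p_eta)
  if (!all(dim(eta) == dim(p_eta)) || nrow(eta) != nm)
    stop("chain arrays must be n_modes x chain_length and congruent")
  structure(list(point = point, eta = eta, p_eta = p_eta),
            class = "qcl_extended_point")
}

check_ext_dims <- function(ext, nhc) {
  if (nrow(ext$eta) != nhc$n_modes || ncol(ext$eta) != nhc$chain_length)
    stop(sprintf("extended point chains are %d x %d but the NHC spec is %d x %d",
                 nrow(ext$eta), ncol(ext$eta), nhc$n_modes, nhc$chain_length))
}

#' Mixed Weyl symbol of the extended (thermostatted) energy
#'
#' `H_e = H(X) + sum_{I,L} P_etaL^2/(2 M_etaL) + sum_{I,L} T(I) eta_L^(I)`.
#' The classical piece (mode kinetic + potential energy, coupling-free, plus
#' all chain terms) is returned as a scalar; the subsystem piece
#' (`h_s` minus the bilinear couplings at the point) as a Hermitian matrix.
#' `H_e` is exactly conserved by the thermostatted flow.
#'
#' @param ext An [extended_point()].
#' @param symbol Symbol from [assemble_hamiltonian()].
#' @param nhc A [nhc_spec()].
#' @return List with `scalar` (number) and `matrix` (`n x n` Hermitian);
#'   `total` is the symbol `scalar * Id + matrix`.
#' @export
extended_energy <- function(ext, symbol, nhc) {
  stopifnot(inherits(ext, "qcl_extended_point"), inherits(symbol, "qcl_symbol"),
            inherits(nhc, "qcl_nhc"))
  check_ext_dims(ext, nhc)
  pt <- ext$point
  if (length(pt$r) != symbol$n_modes)
    stop("extended point and symbol disagree on the number of modes")
  if (symbol$n_modes != nhc$n_modes)
    stop("NHC spec and symbol disagree on the number of modes")
  scalar <- sum(pt$p^2) / 2 + sum(symbol$omega^2 * pt$r^2) / 2 +
    sum(ext$p_eta^2 / (2 * nhc$masses)) +
    sum(nhc$targets * rowSums(ext$eta))
  mat <- symbol$sub$h_s
  ops <- list(symbol$sub$chi, symbol$sub$zeta)
  for (j in seq_len(symbol$n_modes))
    mat <- mat - symbol$coupling[j] * pt$r[j] * ops[[symbol$which_op[j]]]
  list(scalar = scalar, matrix = hermitize(mat),
       total = scalar * diag(1 + 0i, symbol$n) + hermitize(mat))
}

## Index layout of the extended coordinate vector:
## (R_1..R_N, eta_1^(1)..eta_L^(1), ..., eta_L^(N),  P_1..P_N, Peta...).
ext_layout <- function(nhc) {
  nm <- nhc$n_modes; M <- nhc$chain_length
  half <- nm * (1 + M)
  list(nm = nm, M = M, half = half, dim = 2L * half,
       i_r = seq_len(nm),
       i_eta = function(I, L) nm + (I - 1L) * M + L,
       i_p = half + seq_len(nm),
       i_peta = function(I, L) half + nm + (I - 1L) * M + L)
}

#' Antisymmetric structure matrix of the thermostatted dynamics
#'
#' Returns the exactly antisymmetric matrix `B(X_e)` over the extended
#' coordinates `(R, eta; P, P_eta)` such that the equations of motion are
#' `dX_e/dt = B %*% grad H_e`.  With all momenta at rest the matrix reduces to
#' the block-symplectic pattern of [lambda_matrix()] extended over the chains.
#'
#' @inheritParams extended_energy
#' @return Antisymmetric square matrix of side `2 * n_modes * (1 + chain_length)`.
#' @export
nhc_structure_matrix <- function(ext, nhc) {
  stopifnot(inherits(ext, "qcl_extended_point"), inherits(nhc, "qcl_nhc"))
  check_ext_dims(ext, nhc)
  lay <- ext_layout(nhc)
  B <- matrix(0, lay$dim, lay$dim)
  B[seq_len(lay$half), lay$half + seq_len(lay$half)] <- diag(lay$half)
  B[lay$half + seq_len(lay$half), seq_len(lay$half)] <- -diag(lay$half)
  p <- ext$point$p
  for (I in seq_len(lay$nm)) {
    ip <- lay$i_p[I]
    ip1 <- lay$i_peta(I, 1L)
    B[ip, ip1] <- -p[I]          # friction on the physical momentum
    B[ip1, ip] <- p[I]
    if (lay$M > 1) for (L in seq_len(lay$M - 1L)) {
      a <- lay$i_peta(I, L); b <- lay$i_peta(I, L + 1L)
      B[a, b] <- -ext$p_eta[I, L]
      B[b, a] <- ext$p_eta[I, L]
    }
  }
  B
}

## Gradient of H_e over the extended coordinates in ext_layout order;
## surface_force gives -dH/dR per mode (classical scalar force).
ext_gradient <- function(ext, symbol, nhc, surface_force) {
  lay <- ext_layout(nhc)
  g <- numeric(lay$dim)
  g[lay$i_r] <- -surface_force
  g[lay$i_p] <- ext$point$p
  for (I in seq_len(lay$nm)) for (L in seq_len(lay$M)) {
    g[lay$i_eta(I, L)] <- nhc$targets[I]
    g[lay$i_peta(I, L)] <- ext$p_eta[I, L] / nhc$masses[I, L]
  }
  g
}

#' Time derivative of an extended point under the thermostatted flow
#'
#' Evaluates the NHC equations of motion (see the module header) given the
#' classical surface force per mode; equals
#' `nhc_structure_matrix(ext, nhc) %*% grad H_e` by construction.
#'
#' @inheritParams extended_energy
#' @param surface_force Numeric vector, classical force `-dH/dR` per mode
#'   (e.g. an adiabatic-surface or mean-field force).
#' @return List with fields `r`, `p`, `eta`, `p_eta` holding the derivatives.
#' @export
extended_eom <- function(ext, symbol = NULL, nhc, surface_force) {
  stopifnot(inherits(ext, "qcl_extended_point"), inherits(nhc, "qcl_nhc"))
  check_ext_dims(ext, nhc)
  nm <- nhc$n_modes; M <- nhc$chain_length
  surface_force <- rep_len(as.numeric(surface_force), nm)
  p <- ext$point$p
  dr <- p
  dp <- surface_force - p * ext$p_eta[, 1] / nhc$masses[, 1]
  deta <- ext$p_eta / nhc$masses
  dpeta <- matrix(0, nm, M)
  for (L in seq_len(M)) {
    gl <- if (L == 1) p^2 - nhc$targets
          else ext$p_eta[, L - 1]^2 / nhc$masses[, L - 1] - nhc$targets
    drag <- if (L < M) ext$p_eta[, L] * ext$p_eta[, L + 1] / nhc$masses[, L + 1]
            else 0
    dpeta[, L] <- gl - drag
  }
  list(r = dr, p = dp, eta = deta, p_eta = dpeta)
}

#' Integrate thermostatted (or bare) harmonic-mode dynamics
#'
#' Advances every ensemble member with the time-reversible splitting
#' NHC(dt/2) -> exact harmonic rotation(dt) -> NHC(dt/2); the chain update
#' uses a 7-point Suzuki-Yoshida composition.  The subsystem enters through
#' the mean coupling force `C_J <chi>` (expectation in the attached density
#' matrix `w_s`, default the ground state of `h_s`), so the classical modes
#' see a constant bilinear shift; use [sstp_propagate()] for dynamics with
#' quantum back-reaction.
#'
#' @param ensemble A `qcl_ensemble` from [sample_initial_conditions()].
#' @param symbol Symbol from [assemble_hamiltonian()].
#' @param nhc A [nhc_spec()], or `NULL` to integrate without thermostats.
#' @param dt Time step (> 0).
#' @param n_steps Number of steps.
#' @param record_every Record the trajectory every this many steps
#'   (0 = no trajectory, state and running averages only).
#' @param overflow_guard Chain-momentum magnitude that triggers a step
#'   rejection signalling an unstable `dt` (default `1e8`).
#' @return The ensemble advanced in time, with a `record` field per run:
#'   `times`, arrays `r`, `p` (`n_rec x n_modes x n_members`), extended-energy
#'   trace `he`, per-member relative energy drift `drift`, and the per-mode
#'   time-average of `P^2` over all steps (`p2_time_avg`, member-averaged).
#' @export
integrate_nhc <- function(ensemble, symbol, nhc, dt, n_steps,
                          record_every = 0L, overflow_guard = 1e8) {
  stopifnot(inherits(ensemble, "qcl_ensemble"), inherits(symbol, "qcl_symbol"))
  if (dt <= 0) stop("'dt' must be positive")
  n_steps <- as.integer(n_steps)
  nm <- ensemble$n_modes
  if (nm != symbol$n_modes)
    stop("ensemble and symbol disagree on the number of modes")
  thermo <- !is.null(nhc)
  if (thermo) {
    stopifnot(inherits(nhc, "qcl_nhc"))
    if (nhc$n_modes != nm) stop("NHC spec has the wrong number of modes")
    M <- nhc$chain_length
    masses <- nhc$masses; targets <- nhc$targets
  } else {
    M <- if (!is.null(ensemble$eta)) dim(ensemble$eta)[3] else 2L
    masses <- matrix(1, nm, M); targets <- rep(1, nm)
  }
  if (is.null(ensemble$eta)) {
    ensemble$eta <- array(0, c(ensemble$n_samples, nm, M))
    ensemble$p_eta <- array(0, c(ensemble$n_samples, nm, M))
  }
  w_s <- ensemble$w_s
  if (is.null(w_s)) w_s <- ground_state_density(symbol$sub$h_s)
  ops <- list(symbol$sub$chi, symbol$sub$zeta)
  cext <- vapply(seq_len(nm), function(j)
    symbol$coupling[j] *
      Re(sum(diag(w_s %*% ops[[symbol$which_op[j]]]))), numeric(1))

  n_rec <- if (record_every > 0) n_steps %/% record_every else 0L
  rec_r <- if (n_rec > 0) array(0, c(n_rec, nm, ensemble$n_samples)) else NULL
  rec_p <- rec_r
  rec_he <- if (n_rec > 0) matrix(0, n_rec, ensemble$n_samples) else NULL
  drift <- numeric(ensemble$n_samples)
  p2avg <- matrix(0, ensemble$n_samples, nm)
  times <- NULL

  for (m in seq_len(ensemble$n_samples)) {
    emat <- matrix(ensemble$eta[m, , ], nm, M)
    pemat <- matrix(ensemble$p_eta[m, , ], nm, M)
    out <- nhc_integrate_cpp(
      ensemble$r[m, ], ensemble$p[m, ],
      as.numeric(t(emat)), as.numeric(t(pemat)),
      symbol$omega, cext, as.numeric(t(masses)), targets,
      dt, n_steps, thermo, as.integer(record_every), overflow_guard)
    if (isTRUE(out$overflow))
      stop(sprintf(paste0("member %d: chain momentum exceeded the overflow ",
                          "guard %g; reduce dt"), m, overflow_guard))
    ensemble$r[m, ] <- out$r
    ensemble$p[m, ] <- out$p
    ensemble$eta[m, , ] <- matrix(out$eta, nm, M, byrow = TRUE)
    ensemble$p_eta[m, , ] <- matrix(out$p_eta, nm, M, byrow = TRUE)
    p2avg[m, ] <- out$p2_mean
    scale <- max(abs(out$he0), 1e-12)
    drift[m] <- (out$he_max - out$he_min) / scale
    if (n_rec > 0) {
      rec_r[, , m] <- out$traj_r
      rec_p[, , m] <- out$traj_p
      rec_he[, m] <- out$traj_he
      times <- out$traj_t
    }
  }
  ensemble$time <- ensemble$time + n_steps * dt
  ensemble$record <- list(times = times, r = rec_r, p = rec_p, he = rec_he,
                          drift = drift,
                          p2_time_avg = colMeans(p2avg))
  ensemble
}

ground_state_density <- function(h_s) {
  es <- eigen(hermitize(h_s), symmetric = TRUE)
  v <- es$vectors[, which.min(es$values)]
  v %*% Conj(t(v))
}

#' Build zero-point (or thermal) thermostat targets for a model
#'
#' Convenience wrapper: `T(I) = 1/effective_beta(beta, omega_I)` per mode of
#' the assembled symbol.
#'
#' @param symbol Symbol from [assemble_hamiltonian()].
#' @param thermal A [thermal_spec()]; classical regime gives `T(I) = 1/beta`.
#' @param chain_length,masses Passed to [nhc_spec()]; by default the masses
#'   are set per mode to `T(I) / (2 omega_I)^2` (chain relaxation time
#'   `1/(2 omega_I)`), which samples stiff harmonic modes ergodically.
#' @return A [nhc_spec()].
#' @export
nhc_spec_for <- function(symbol, thermal, chain_length = 2L, masses = NULL) {
  stopifnot(inherits(symbol, "qcl_symbol"), inherits(thermal, "qcl_thermal"))
  targets <- if (thermal$regime == "classical") rep(1 / thermal$beta, symbol$n_modes)
             else 1 / effective_beta(thermal$beta, symbol$omega)
  ## chain relaxation time tau_I = 1/(2 omega_I): couples the chain faster
  ## than the mode period, which de-correlates the stiff harmonic motion
  if (is.null(masses))
    masses <- matrix(targets / (2 * symbol$omega)^2, symbol$n_modes,
                     chain_length)
  nhc_spec(symbol$n_modes, targets, chain_length = chain_length, masses = masses)
}
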