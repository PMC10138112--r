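## Propagation of mixed Weyl symbols under the quantum-classical bracket
##   dO/dt = i[H, O] - (1/2)(H <-grad Lambda grad-> O - O <-grad Lambda grad-> H)
## (Heisenberg sign; the statistical symbol W evolves with the opposite sign).
## Two solvers:
##  - a finite-difference (R, P) grid solver, the verifiable reference for
##    small subsystems coupled to one classical mode, and
##  - an adiabatic-basis trajectory solver with optional momentum-jump
##    nonadiabatic transitions (sequential short-time propagation), for
##    ensembles and larger banks.

#' Phase-space grid state
#'
#' An `n x n` matrix field over a rectangular `(R, P)` lattice, holding the
#' mixed Weyl symbol of either an observable or a statistical operator.
#'
#' @param r_grid,p_grid Uniformly spaced coordinate/momentum grids.
#' @param rho Complex array `dim = c(n, n, length(r_grid), length(p_grid))`,
#'   Hermitian in its first two indices at every node.
#' @param time Current time.
#' @return Object of class `qcl_grid_state`.
#' @export
grid_state <- function(r_grid, p_grid, rho, time = 0) {
  r_grid <- as.numeric(r_grid); p_grid <- as.numeric(p_grid)
  stopifnot(length(r_grid) >= 5, length(p_grid) >= 5)
  if (max(abs(diff(diff(r_grid)))) > 1e-10 * mean(abs(diff(r_grid))) ||
      max(abs(diff(diff(p_grid)))) > 1e-10 * mean(abs(diff(p_grid))))
    stop("grids must be uniformly spaced")
  d <- dim(rho)
  if (length(d) != 4 || d[1] != d[2] || d[3] != length(r_grid) ||
      d[4] != length(p_grid))
    stop("'rho' must have dim c(n, n, length(r_grid), length(p_grid))")
  storage.mode(rho) <- "complex"
  structure(list(r_grid = r_grid, p_grid = p_grid, rho = rho, time = time,
                 n = d[1], boundary_flag = FALSE),
            class = "qcl_grid_state")
}

#' Initial grid state for a thermalized one-mode model
#'
#' Builds `W(R, P) = w_s * W_beta(R, P)` on a lattice spanning
#' `n_widths` thermal standard deviations in each direction.
#'
#' @param symbol One-mode symbol from [assemble_hamiltonian()].
#' @param thermal A [thermal_spec()].
#' @param w_s Subsystem density matrix; default ground state of `h_s`.
#' @param n_r,n_p Lattice size (default 64 x 64).
#' @param n_widths Half-extent in thermal widths (default 6).
#' @return A [grid_state()] (statistical symbol, unit trace functional).
#' @export
initial_grid_state <- function(symbol, thermal, w_s = NULL,
                               n_r = 64, n_p = 64, n_widths = 6) {
  stopifnot(inherits(symbol, "qcl_symbol"))
  if (symbol$n_modes != 1)
    stop("the grid solver handles exactly one classical mode")
  if (is.null(w_s)) w_s <- ground_state_density(symbol$sub$h_s)
  w_s <- validate_density_matrix(w_s)
  mom <- wigner_thermal_moments(thermal, symbol$omega)
  rg <- seq(-n_widths * sqrt(mom$var_r), n_widths * sqrt(mom$var_r),
            length.out = n_r)
  pg <- seq(-n_widths * sqrt(mom$var_p), n_widths * sqrt(mom$var_p),
            length.out = n_p)
  dens <- outer(dnorm(rg, sd = sqrt(mom$var_r)),
                dnorm(pg, sd = sqrt(mom$var_p)))
  n <- symbol$n
  rho <- array(0 + 0i, c(n, n, n_r, n_p))
  for (a in seq_len(n)) for (b in seq_len(n))
    rho[a, b, , ] <- w_s[a, b] * dens
  grid_state(rg, pg, rho, time = 0)
}

#' Uniform constant matrix field over a grid
#'
#' Embeds a phase-space-independent observable matrix on the lattice of an
#' existing grid state (e.g. to evolve it in the Heisenberg picture).
#'
#' @param template A [grid_state()] supplying the lattice.
#' @param matrix_part Hermitian `n x n` matrix.
#' @param classical_part Optional function `f(R, P)` multiplying the identity.
#' @return A [grid_state()].
#' @export
uniform_grid_observable <- function(template, matrix_part,
                                    classical_part = NULL) {
  stopifnot(inherits(template, "qcl_grid_state"))
  m <- as_complex_matrix(matrix_part)
  n <- nrow(m)
  rho <- array(0 + 0i, c(n, n, length(template$r_grid), length(template$p_grid)))
  for (a in seq_len(n)) for (b in seq_len(n)) rho[a, b, , ] <- m[a, b]
  if (!is.null(classical_part)) {
    f <- outer(template$r_grid, template$p_grid, classical_part)
    for (a in seq_len(n)) rho[a, a, , ] <- rho[a, a, , ] + f
  }
  grid_state(template$r_grid, template$p_grid, rho, time = template$time)
}

grid_model_parts <- function(symbol) {
  if (symbol$n_modes != 1)
    stop("the grid solver handles exactly one classical mode")
  op <- if (symbol$which_op[1] == 1L) symbol$sub$chi else symbol$sub$zeta
  list(h0 = symbol$sub$h_s, op = op, omega = symbol$omega[1],
       coupling = symbol$coupling[1])
}

#' Boundary mass fraction of a grid state
#'
#' Fraction of the trace-norm mass carried by the two outermost lattice
#' shells; large values mean the grid is too narrow for the state.
#'
#' @param state A [grid_state()].
#' @return Number in `[0, 1]`.
#' @export
boundary_mass <- function(state) {
  tr <- abs(trace_field(state))
  nr <- length(state$r_grid); np <- length(state$p_grid)
  edge <- matrix(FALSE, nr, np)
  edge[c(1, 2, nr - 1, nr), ] <- TRUE
  edge[, c(1, 2, np - 1, np)] <- TRUE
  tot <- sum(tr)
  if (tot == 0) return(0)
  sum(tr[edge]) / tot
}

trace_field <- function(state) {
  n <- state$n
  f <- state$rho[1, 1, , ]
  if (n > 1) for (a in 2:n) f <- f + state$rho[a, a, , ]
  f
}

#' Trace functional of a grid state
#'
#' `Tr' integral dR dP rho(R, P)`; equals 1 for a normalized statistical
#' symbol and is conserved by [propagate_grid()].
#'
#' @param state A [grid_state()].
#' @return Real number.
#' @export
trace_functional <- function(state) {
  hr <- diff(state$r_grid[1:2]); hp <- diff(state$p_grid[1:2])
  Re(sum(trace_field(state))) * hr * hp
}

#' Right-hand side of the quantum-classical bracket on the grid
#'
#' Evaluates the bracket with 4th-order central phase-space differences.
#' `picture = "heisenberg"` gives the observable sign of the equation of
#' motion; `"schrodinger"` the opposite sign for statistical symbols.
#'
#' @param state A [grid_state()].
#' @param symbol One-mode symbol from [assemble_hamiltonian()].
#' @param picture `"heisenberg"` or `"schrodinger"`.
#' @param boundary_tol Boundary-mass fraction above which the state is
#'   flagged (checked for statistical symbols).
#' @return A [grid_state()]-shaped object holding the time derivative.
#' @export
qc_bracket_rhs <- function(state, symbol,
                           picture = c("heisenberg", "schrodinger"),
                           boundary_tol = 1e-8) {
  picture <- match.arg(picture)
  stopifnot(inherits(state, "qcl_grid_state"), inherits(symbol, "qcl_symbol"))
  parts <- grid_model_parts(symbol)
  if (state$n != symbol$n) stop("state and symbol dimensions differ")
  sign <- if (picture == "heisenberg") 1 else -1
  flagged <- FALSE
  if (picture == "schrodinger" && boundary_mass(state) > boundary_tol)
    flagged <- TRUE
  out <- qcle_rhs_cpp(as.complex(state$rho), parts$h0, parts$op,
                      parts$omega, parts$coupling,
                      state$r_grid, state$p_grid, sign)
  res <- grid_state(state$r_grid, state$p_grid,
                    array(out, dim(state$rho)), time = state$time)
  res$boundary_flag <- flagged
  res
}

#' CFL-type step bound of a grid/symbol pair
#'
#' `0.6 * min(h_R / max|P|, h_P / max|F|)` with the force bound taken over
#' the lattice corners and adiabatic surfaces.
#'
#' @inheritParams qc_bracket_rhs
#' @return Suggested maximal stable `dt`.
#' @export
grid_cfl_limit <- function(state, symbol) {
  parts <- grid_model_parts(symbol)
  hr <- diff(state$r_grid[1:2]); hp <- diff(state$p_grid[1:2])
  pmax <- max(abs(state$p_grid))
  rmax <- max(abs(state$r_grid))
  fmax <- parts$omega^2 * rmax + abs(parts$coupling) * max(abs(parts$op), 1e-12) +
    .Machine$double.eps
  0.6 * min(hr / max(pmax, 1e-12), hp / fmax)
}

#' Propagate a grid state under the quantum-classical bracket
#'
#' RK4 in time, 4th-order central differences in phase space, node-wise
#' re-Hermitization each step.  Rejects time steps above the CFL-type bound
#' of [grid_cfl_limit()].
#'
#' @inheritParams qc_bracket_rhs
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @param absorb Damping rate of the 4-cell absorbing boundary layer that
#'   stabilizes the zero-ghost finite differences (0 disables it); it only
#'   affects lattice cells where a well-resolved state has negligible mass.
#' @return The advanced [grid_state()].
#' @export
propagate_grid <- function(state, symbol, dt, n_steps,
                           picture = c("heisenberg", "schrodinger"),
                           absorb = 10) {
  picture <- match.arg(picture)
  stopifnot(inherits(state, "qcl_grid_state"), inherits(symbol, "qcl_symbol"))
  parts <- grid_model_parts(symbol)
  lim <- grid_cfl_limit(state, symbol)
  if (dt > lim)
    stop(sprintf("dt = %g exceeds the grid stability bound; use dt <= %g",
                 dt, lim))
  sign <- if (picture == "heisenberg") 1 else -1
  out <- qcle_propagate_cpp(as.complex(state$rho), parts$h0, parts$op,
                            parts$omega, parts$coupling,
                            state$r_grid, state$p_grid, dt,
                            as.integer(n_steps), sign, absorb)
  res <- grid_state(state$r_grid, state$p_grid, array(out, dim(state$rho)),
                    time = state$time + n_steps * dt)
  res$boundary_flag <- state$boundary_flag
  res
}

## ---------------------------------------------------------------------------
## Adiabatic-basis trajectory solver (sequential short-time propagation)
## ---------------------------------------------------------------------------

## Batched Hermitian 2x2 eigensystem from component vectors; ascending
## energies, columns phase-fixed (largest-magnitude component real positive).
eig2_batch <- function(h11, h12, h22) {
  m <- Re(h11 + h22) / 2
  d <- Re(h11 - h22) / 2
  gap2 <- sqrt(d^2 + Mod(h12)^2)
  e1 <- m - gap2; e2 <- m + gap2
  small <- Mod(h12) < 1e-14 * pmax(abs(m) + gap2, 1)
  ## eigenvector of e1: (h12, e1 - h11); of e2: (e2 - h22, Conj(h12))
  v11 <- h12;           v21 <- e1 - h11
  v12 <- e2 - h22;      v22 <- Conj(h12)
  ## degenerate/diagonal case: pick basis vectors ordered by diagonal
  lo_first <- Re(h11) <= Re(h22)
  v11[small] <- ifelse(lo_first[small], 1 + 0i, 0 + 0i)
  v21[small] <- ifelse(lo_first[small], 0 + 0i, 1 + 0i)
  v12[small] <- ifelse(lo_first[small], 0 + 0i, 1 + 0i)
  v22[small] <- ifelse(lo_first[small], 1 + 0i, 0 + 0i)
  nrm1 <- sqrt(Mod(v11)^2 + Mod(v21)^2)
  nrm2 <- sqrt(Mod(v12)^2 + Mod(v22)^2)
  v11 <- v11 / nrm1; v21 <- v21 / nrm1
  v12 <- v12 / nrm2; v22 <- v22 / nrm2
  ph1 <- ifelse(Mod(v11) >= Mod(v21), v11 / pmax(Mod(v11), 1e-300),
                v21 / pmax(Mod(v21), 1e-300))
  ph2 <- ifelse(Mod(v12) >= Mod(v22), v12 / pmax(Mod(v12), 1e-300),
                v22 / pmax(Mod(v22), 1e-300))
  v11 <- v11 / ph1; v21 <- v21 / ph1
  v12 <- v12 / ph2; v22 <- v22 / ph2
  list(e1 = e1, e2 = e2, v11 = v11, v21 = v21, v12 = v12, v22 = v22)
}

## Subsystem matrix h_eff(X) = h_s - s1 chi - s2 zeta per member, where
## s1/s2 are the coupling-weighted coordinate sums of each bank.
coupling_sums <- function(symbol, r) {
  cj <- symbol$coupling
  s1 <- if (any(symbol$which_op == 1L))
    r[, symbol$which_op == 1L, drop = FALSE] %*% cj[symbol$which_op == 1L]
  else 0
  s2 <- if (any(symbol$which_op == 2L))
    r[, symbol$which_op == 2L, drop = FALSE] %*% cj[symbol$which_op == 2L]
  else 0
  list(s1 = as.numeric(s1), s2 = as.numeric(s2))
}

## Adiabatic data per member (n = 2 vectorized): energies, basis components,
## and adiabatic matrix elements of chi and zeta.
adiabatic_batch2 <- function(symbol, r) {
  cs <- coupling_sums(symbol, r)
  hs <- symbol$sub$h_s; chi <- symbol$sub$chi; zeta <- symbol$sub$zeta
  h11 <- hs[1, 1] - cs$s1 * chi[1, 1] - cs$s2 * zeta[1, 1]
  h12 <- hs[1, 2] - cs$s1 * chi[1, 2] - cs$s2 * zeta[1, 2]
  h22 <- hs[2, 2] - cs$s1 * chi[2, 2] - cs$s2 * zeta[2, 2]
  eg <- eig2_batch(h11, h12, h22)
  ad_el <- function(op, va1, va2, vb1, vb2)
    Conj(va1) * (op[1, 1] * vb1 + op[1, 2] * vb2) +
    Conj(va2) * (op[2, 1] * vb1 + op[2, 2] * vb2)
  mk <- function(op) list(
    e11 = ad_el(op, eg$v11, eg$v21, eg$v11, eg$v21),
    e22 = ad_el(op, eg$v12, eg$v22, eg$v12, eg$v22),
    e12 = ad_el(op, eg$v11, eg$v21, eg$v12, eg$v22))
  c(eg, list(chi_ad = mk(chi), zeta_ad = mk(zeta)))
}

## Mean-surface force per coordinate for members in pair (a, b):
## F_j = -omega_j^2 R_j + c_j * (op_aa + op_bb)/2  (Hellmann-Feynman).
mean_surface_force <- function(symbol, r, ad, a, b) {
  nm <- symbol$n_modes
  diag_of <- function(op_ad, idx)
    ifelse(idx == 1L, Re(op_ad$e11), Re(op_ad$e22))
  mean1 <- (diag_of(ad$chi_ad, a) + diag_of(ad$chi_ad, b)) / 2
  mean2 <- (diag_of(ad$zeta_ad, a) + diag_of(ad$zeta_ad, b)) / 2
  f <- matrix(0, nrow(r), nm)
  for (j in seq_len(nm)) {
    mj <- if (symbol$which_op[j] == 1L) mean1 else mean2
    f[, j] <- -symbol$omega[j]^2 * r[, j] + symbol$coupling[j] * mj
  }
  f
}

energy_of_index <- function(ad, idx) ifelse(idx == 1L, ad$e1, ad$e2)

#' Adiabatic-basis trajectory propagation (sequential short-time scheme)
#'
#' Each ensemble member carries a pair of adiabatic indices `(a, b)`
#' representing a matrix element of the evolving Heisenberg symbol.  Classical
#' coordinates move by velocity Verlet on the mean surface `(E_a + E_b)/2`; a
#' phase `exp(+i int (E_a - E_b) dt)` accumulates (trapezoid rule).  In
#' `"nonadiabatic"` mode, transitions of either index are sampled each step
#' from the nonadiabatic coupling `P . d_ab`, with momentum-jump energy
#' adjustment along the coupling direction and importance weights; frustrated
#' or cut-off members are frozen and flagged.  Currently implemented for
#' two-level subsystems.
#'
#' @param ensemble A `qcl_ensemble` from [sample_initial_conditions()].
#' @param symbol Symbol from [assemble_hamiltonian()] (`n = 2`).
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @param hop_mode `"adiabatic_only"` (no transitions) or `"nonadiabatic"`.
#' @param seed Integer seed for the transition sampling.
#' @param record_every Record a snapshot every this many steps.
#' @param weight_cutoff Freeze a member when `|weight|` exceeds this
#'   (variance control; default 150).
#' @return Object of class `qcl_sstp` holding the snapshot list (`times`,
#'   per-time `r`, `p`, `a`, `b`, complex amplitude `amp`), the initial
#'   adiabatic data needed by the estimators, and bookkeeping (`n_frozen`).
#' @export
sstp_propagate <- function(ensemble, symbol, dt, n_steps,
                           hop_mode = c("adiabatic_only", "nonadiabatic"),
                           seed = 1L, record_every = 1L,
                           weight_cutoff = 150) {
  hop_mode <- match.arg(hop_mode)
  stopifnot(inherits(ensemble, "qcl_ensemble"), inherits(symbol, "qcl_symbol"))
  if (symbol$n != 2)
    stop("the trajectory solver currently supports two-level subsystems")
  if (ensemble$n_modes != symbol$n_modes)
    stop("ensemble and symbol disagree on the number of modes")
  n <- symbol$n
  N <- ensemble$n_samples
  nm <- ensemble$n_modes
  set.seed(as.integer(seed))

  r <- ensemble$r; p <- ensemble$p
  ## stratified pair assignment: member m gets pair ((m-1) mod n^2)
  pair <- (seq_len(N) - 1L) %% (n * n)
  a <- pair %/% n + 1L
  b <- pair %% n + 1L
  a0 <- a; b0 <- b
  w <- rep(1, N)
  phase <- rep(1 + 0i, N)
  frozen <- rep(FALSE, N)

  ad <- adiabatic_batch2(symbol, r)
  basis0 <- list(v11 = ad$v11, v21 = ad$v21, v12 = ad$v12, v22 = ad$v22)
  f <- mean_surface_force(symbol, r, ad, a, b)
  de_old <- energy_of_index(ad, a) - energy_of_index(ad, b)

  n_rec <- n_steps %/% record_every
  times <- numeric(n_rec + 1)
  snap <- vector("list", n_rec + 1)
  snap[[1]] <- list(r = r, p = p, a = a, b = b, amp = w * phase)
  irec <- 1L

  for (s in seq_len(n_steps)) {
    r <- r + dt * p + (dt^2 / 2) * f
    ad_prev <- ad
    ad <- adiabatic_batch2(symbol, r)
    ## Basis continuity along each trajectory.  o_ij = <v_i(new), v_j(old)>.
    ## If the energy-ordered states swapped identity across the step
    ## (trivial crossing: |o11|^2 < 1/2), relabel the member's indices so
    ## they follow the same physical state; and fold any convention phase
    ## or sign jump of the fresh eigenvectors (parallel transport) into the
    ## member amplitude so that matrix elements evaluated in the fresh
    ## basis at any time remain consistent.
    o11 <- Conj(ad$v11) * ad_prev$v11 + Conj(ad$v21) * ad_prev$v21
    o22 <- Conj(ad$v12) * ad_prev$v12 + Conj(ad$v22) * ad_prev$v22
    swapped <- Mod(o11)^2 < 0.5
    if (any(swapped)) {
      o21 <- Conj(ad$v12) * ad_prev$v11 + Conj(ad$v22) * ad_prev$v21
      o12 <- Conj(ad$v11) * ad_prev$v12 + Conj(ad$v21) * ad_prev$v22
      u1 <- ifelse(swapped, o21, o11)   # continuity factor of old state 1
      u2 <- ifelse(swapped, o12, o22)
    } else {
      u1 <- o11; u2 <- o22
    }
    lam1 <- Conj(u1) / pmax(Mod(u1), 1e-300)
    lam2 <- Conj(u2) / pmax(Mod(u2), 1e-300)
    lam_a <- ifelse(a == 1L, lam1, lam2)   # indices before relabelling
    lam_b <- ifelse(b == 1L, lam1, lam2)
    phase <- phase * lam_a * Conj(lam_b)
    if (any(swapped)) {
      a[swapped] <- 3L - a[swapped]
      b[swapped] <- 3L - b[swapped]
      de_old[swapped] <- -de_old[swapped]
    }
    f_new <- mean_surface_force(symbol, r, ad, a, b)
    p <- p + (dt / 2) * (f + f_new)
    f <- f_new
    de_new <- energy_of_index(ad, a) - energy_of_index(ad, b)
    phase <- phase * exp(1i * dt * (de_old + de_new) / 2)
    de_old <- de_new

    if (hop_mode == "nonadiabatic") {
      hop <- attempt_hops2(symbol, r, p, ad, a, b, w, frozen, dt)
      changed <- hop$a != a | hop$b != b
      if (any(changed)) {
        a <- hop$a; b <- hop$b; p <- hop$p; w <- hop$w
        ## surfaces changed: refresh force and phase slope
        f <- mean_surface_force(symbol, r, ad, a, b)
        de_old <- energy_of_index(ad, a) - energy_of_index(ad, b)
      } else w <- hop$w
      frozen <- frozen | abs(w) > weight_cutoff
    }

    if (s %% record_every == 0) {
      irec <- irec + 1L
      times[irec] <- s * dt
      snap[[irec]] <- list(r = r, p = p, a = a, b = b, amp = w * phase)
    }
  }

  w_s <- ensemble$w_s
  if (is.null(w_s)) w_s <- ground_state_density(symbol$sub$h_s)
  structure(list(times = times[seq_len(irec)], snapshots = snap[seq_len(irec)],
                 a0 = a0, b0 = b0, basis0 = basis0, w_s = w_s,
                 n = n, n_samples = N, n_modes = nm, symbol = symbol,
                 hop_mode = hop_mode, seed = as.integer(seed),
                 n_frozen = sum(frozen)),
            class = "qcl_sstp")
}

## One round of momentum-jump transition attempts for both indices (n = 2).
## The nonadiabatic coupling between the two adiabatic states along
## coordinate j is d_j = <1|dH/dR_j|2> / (e2 - e1) = -c_j op12 / (e2 - e1).
attempt_hops2 <- function(symbol, r, p, ad, a, b, w, frozen, dt) {
  N <- length(a); nm <- symbol$n_modes
  gap <- ad$e2 - ad$e1
  ## P . d summed over coordinates (real for real models; Re taken for the
  ## sampling magnitude, full value enters the weight)
  pd12 <- rep(0 + 0i, N)
  dvec <- matrix(0, N, nm)   # Re(d_j), direction of the momentum jump
  for (j in seq_len(nm)) {
    op12 <- if (symbol$which_op[j] == 1L) ad$chi_ad$e12 else ad$zeta_ad$e12
    dj <- -symbol$coupling[j] * op12 / gap
    dvec[, j] <- Re(dj)
    pd12 <- pd12 + p[, j] * dj
  }
  for (which in c("a", "b")) {
    idx <- if (which == "a") a else b
    ## coupling element for the current index towards the other state:
    ## d_{12} for 1 -> 2, d_{21} = -Conj(d_{12}) for 2 -> 1; the second
    ## (bra) index enters through the conjugate element
    pd <- ifelse(idx == 1L, pd12, -Conj(pd12))
    if (which == "b") pd <- Conj(pd)
    g <- abs(dt * Re(pd))
    pi_hop <- g / (1 + g)
    u <- stats::runif(N)
    try_hop <- !frozen & u < pi_hop & g > 0
    ## energy change of the mean surface if this index flips
    target <- 3L - idx
    dpot <- (energy_of_index(ad, target) - energy_of_index(ad, idx)) / 2
    if (any(try_hop)) {
      dn2 <- rowSums(dvec^2)
      dn2[dn2 == 0] <- 1e-300
      ppar <- rowSums(p * dvec) / sqrt(dn2)
      disc <- ppar^2 - 2 * dpot
      ok <- try_hop & disc >= 0
      ## accepted hops: flip index, rescale momentum along d, reweight
      if (any(ok)) {
        ppar_new <- sign(ppar[ok]) * sqrt(disc[ok])
        scale <- (ppar_new - ppar[ok]) / sqrt(dn2[ok])
        p[ok, ] <- p[ok, , drop = FALSE] + dvec[ok, , drop = FALSE] * scale
        if (which == "a") a[ok] <- target[ok] else b[ok] <- target[ok]
        w[ok] <- w[ok] * dt * Re(pd[ok]) / pi_hop[ok]
      }
      ## frustrated attempts fall through to the no-hop branch
      try_hop <- ok
    }
    no_hop <- !frozen & !try_hop & pi_hop < 1
    w[no_hop] <- w[no_hop] / (1 - pi_hop[no_hop])
  }
  list(a = a, b = b, p = p, w = w)
}

#' @export
print.qcl_sstp <- function(x, ...) {
  cat(sprintf("<qcl_sstp> %d member(s), %d snapshot(s), mode = %s, frozen = %d\n",
              x$n_samples, length(x$times), x$hop_mode, x$n_frozen))
  invisible(x)
}
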