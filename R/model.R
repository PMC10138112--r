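## Model assembly: quantum subsystem, harmonic mode banks, and the mixed Weyl
## symbol of the total Hamiltonian
##   H~(X) = H_S + sum_J (P_J^2/2 + omega_J^2 R_J^2/2) Id
##               - sum_J C_J R_J chi        (phonon bank)
##               - sum_K F_K Q_K zeta       (EM bank)
## in hbar = k_B = m = 1 units.

.HERM_TOL <- 1e-12

is_hermitian <- function(m, tol = .HERM_TOL) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  scale <- max(abs(m), 1)
  max(abs(m - Conj(t(m)))) <= tol * scale
}

hermitize <- function(m) (m + Conj(t(m))) / 2

#' Quantum subsystem specification
#'
#' Bundles the subsystem Hamiltonian `h_s` together with the two dimensionless
#' Hermitian coupling operators: `chi` couples to the phonon bank, `zeta` to
#' the electromagnetic-field bank.
#'
#' @param h_s Hermitian `n x n` matrix, energy units (hbar = 1).
#' @param chi Hermitian `n x n` matrix; default zero (no phonon coupling).
#' @param zeta Hermitian `n x n` matrix; default zero (no EM coupling).
#' @return An object of class `qcl_subsystem` with fields `n`, `h_s`, `chi`,
#'   `zeta`.
#' @examples
#' sub <- subsystem_spec(h_s = diag(c(1, -1)), chi = diag(c(1, -1)))
#' @export
subsystem_spec <- function(h_s, chi = NULL, zeta = NULL) {
  h_s <- as_complex_matrix(h_s, "h_s")
  n <- nrow(h_s)
  if (n < 1) stop("subsystem dimension must be >= 1")
  if (is.null(chi)) chi <- matrix(0 + 0i, n, n)
  if (is.null(zeta)) zeta <- matrix(0 + 0i, n, n)
  chi <- as_complex_matrix(chi, "chi")
  zeta <- as_complex_matrix(zeta, "zeta")
  for (nm in c("h_s", "chi", "zeta")) {
    m <- get(nm)
    if (nrow(m) != n || ncol(m) != n)
      stop(sprintf("'%s' must be %d x %d", nm, n, n))
    if (!is_hermitian(m))
      stop(sprintf("'%s' is not Hermitian within tolerance %g", nm, .HERM_TOL))
  }
  structure(list(n = n, h_s = h_s, chi = chi, zeta = zeta),
            class = "qcl_subsystem")
}

as_complex_matrix <- function(m, name = "matrix") {
  if (is.null(dim(m))) {
    if (length(m) == 1) m <- matrix(m, 1, 1)
    else stop(sprintf("'%s' must be a square matrix", name))
  }
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop(sprintf("'%s' must be square", name))
  storage.mode(m) <- "complex"
  m
}

#' Bank of classical harmonic modes
#'
#' A set of harmonic oscillators (unit mass) that enter the Hamiltonian as
#' `P^2/2 + omega^2 R^2/2`, bilinearly coupled to the subsystem through the
#' per-mode coupling constants.
#'
#' @param kind `"phonon"` or `"em"`; determines which subsystem operator
#'   (`chi` or `zeta`) the bank couples to.
#' @param omega Vector of positive mode frequencies (1/time).
#' @param coupling Vector of real coupling constants, same length as `omega`;
#'   default all zero.
#' @return Object of class `qcl_bank`.
#' @examples
#' bank <- oscillator_bank("phonon", omega = 1, coupling = 0.3)
#' @export
oscillator_bank <- function(kind = c("phonon", "em"), omega,
                            coupling = rep(0, length(omega))) {
  kind <- match.arg(kind)
  omega <- as.numeric(omega)
  coupling <- as.numeric(coupling)
  if (length(omega) < 1) stop(sprintf("bank '%s': needs at least one mode", kind))
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop(sprintf("bank '%s': all frequencies must be positive and finite", kind))
  if (length(coupling) != length(omega))
    stop(sprintf("bank '%s': omega and coupling lengths differ (%d vs %d)",
                 kind, length(omega), length(coupling)))
  structure(list(kind = kind, omega = omega, coupling = coupling,
                 n_modes = length(omega)),
            class = "qcl_bank")
}

#' Classical phase-space point
#'
#' Coordinates and momenta of all classical modes, concatenated in bank order
#' (phonon coordinates `R_J` first, then EM coordinates `Q_K`).
#'
#' @param r Coordinates.
#' @param p Conjugate momenta, same length.
#' @return Object of class `qcl_phase_point`.
#' @export
phase_point <- function(r, p) {
  r <- as.numeric(r); p <- as.numeric(p)
  if (length(r) != length(p))
    stop("coordinate and momentum vectors must have equal length")
  structure(list(r = r, p = p), class = "qcl_phase_point")
}

## Concatenated per-coordinate model vectors for the assembled Hamiltonian.
bank_vectors <- function(phonons, em) {
  omega <- c(if (!is.null(phonons)) phonons$omega,
             if (!is.null(em)) em$omega)
  coupling <- c(if (!is.null(phonons)) phonons$coupling,
                if (!is.null(em)) em$coupling)
  which_op <- c(if (!is.null(phonons)) rep(1L, phonons$n_modes),
                if (!is.null(em)) rep(2L, em$n_modes))
  list(omega = omega, coupling = coupling, which_op = which_op)
}

#' Assemble the mixed Weyl symbol of the Hamiltonian
#'
#' Builds the Hermitian-matrix-valued function of the classical phase point
#' `H~(X) = h_s + [sum_J (P_J^2/2 + omega_J^2 R_J^2 / 2)] Id
#'  - sum_J C_J R_J chi - sum_K F_K Q_K zeta`,
#' with the phonon bank coupled through `chi` and the EM bank through `zeta`.
#'
#' @param sub A [subsystem_spec()].
#' @param phonons Optional phonon [oscillator_bank()].
#' @param em Optional EM [oscillator_bank()].
#' @return Object of class `qcl_symbol` with callable fields
#'   `evaluate(point)`, `gradient_r(point)`, `gradient_p(point)` and the model
#'   pieces attached for structure-exploiting solvers.
#' @examples
#' sub <- subsystem_spec(diag(c(1, -1)), chi = diag(c(1, -1)))
#' H <- assemble_hamiltonian(sub, oscillator_bank("phonon", 1, 0.3))
#' H$evaluate(phase_point(1, 0))   # diag(1.2, -0.2)
#' @export
assemble_hamiltonian <- function(sub, phonons = NULL, em = NULL) {
  stopifnot(inherits(sub, "qcl_subsystem"))
  if (!is.null(phonons)) {
    if (!inherits(phonons, "qcl_bank") || phonons$kind != "phonon")
      stop("'phonons' must be an oscillator_bank of kind 'phonon'")
  }
  if (!is.null(em)) {
    if (!inherits(em, "qcl_bank") || em$kind != "em")
      stop("'em' must be an oscillator_bank of kind 'em'")
  }
  if (is.null(phonons) && is.null(em))
    stop("at least one oscillator bank is required")
  bv <- bank_vectors(phonons, em)
  n <- sub$n
  id <- diag(1 + 0i, n)
  ops <- list(sub$chi, sub$zeta)

  check_point <- function(point) {
    if (!inherits(point, "qcl_phase_point")) point <- phase_point(point$r, point$p)
    if (length(point$r) != length(bv$omega))
      stop(sprintf("phase point has %d coordinates but the model has %d modes",
                   length(point$r), length(bv$omega)))
    point
  }

  evaluate <- function(point) {
    point <- check_point(point)
    e_cl <- sum(point$p^2) / 2 + sum(bv$omega^2 * point$r^2) / 2
    m <- sub$h_s + e_cl * id
    for (j in seq_along(bv$omega))
      m <- m - bv$coupling[j] * point$r[j] * ops[[bv$which_op[j]]]
    hermitize(m)
  }
  gradient_r <- function(point) {
    point <- check_point(point)
    lapply(seq_along(bv$omega), function(j)
      bv$omega[j]^2 * point$r[j] * id - bv$coupling[j] * ops[[bv$which_op[j]]])
  }
  gradient_p <- function(point) {
    point <- check_point(point)
    lapply(point$p, function(pj) pj * id)
  }

  structure(list(evaluate = evaluate, gradient_r = gradient_r,
                 gradient_p = gradient_p, n = n, sub = sub,
                 omega = bv$omega, coupling = bv$coupling,
                 which_op = bv$which_op, n_modes = length(bv$omega)),
            class = "qcl_symbol")
}

#' Matrix-valued classical force of an assembled symbol
#'
#' Returns `-dH~/dR_j` for every classical coordinate: per phonon coordinate
#' `-omega_J^2 R_J Id + C_J chi`, analogously with `zeta` for EM coordinates.
#'
#' @param symbol Symbol from [assemble_hamiltonian()].
#' @param point A [phase_point()].
#' @return List of `n x n` Hermitian matrices, one per coordinate.
#' @export
classical_force <- function(symbol, point) {
  stopifnot(inherits(symbol, "qcl_symbol"))
  lapply(symbol$gradient_r(point), function(g) -g)
}

#' Adiabatic eigensystem of a mixed Weyl symbol at a phase point
#'
#' Diagonalizes the Hermitian matrix `symbol$evaluate(point)`.  Energies are
#' returned ascending and each eigenvector's largest-magnitude component is
#' rotated to be real and positive, giving a deterministic phase convention.
#'
#' @param symbol A `qcl_symbol` (or any object with an `evaluate` field).
#' @param point A [phase_point()].
#' @param degeneracy_gap Gap below which the result is flagged nearly
#'   degenerate (default `1e-10`).
#' @return List with `energies` (ascending), `basis` (unitary, columns are
#'   eigenvectors), and `near_degenerate` (logical).
#' @export
adiabatic_eigensystem <- function(symbol, point, degeneracy_gap = 1e-10) {
  m <- symbol$evaluate(point)
  es <- eigen(hermitize(m), symmetric = TRUE)
  ord <- order(es$values)            # ascending
  energies <- es$values[ord]
  basis <- es$vectors[, ord, drop = FALSE]
  basis <- fix_eigvec_phase(basis)
  gaps <- diff(energies)
  list(energies = energies, basis = basis,
       near_degenerate = length(gaps) > 0 && min(gaps) < degeneracy_gap)
}

fix_eigvec_phase <- function(basis) {
  for (k in seq_len(ncol(basis))) {
    v <- basis[, k]
    i <- which.max(abs(v))
    ph <- v[i] / abs(v[i])
    basis[, k] <- v / ph
  }
  basis
}

#' Antisymmetric structure matrices of the quantum-classical bracket
#'
#' `omega_matrix()` is the 2x2 antisymmetric matrix pairing the two terms of
#' the commutator; `lambda_matrix(n)` is the `2n x 2n` symplectic matrix
#' pairing classical coordinates with their momenta (coordinates first).
#'
#' @param n_modes Number of classical modes.
#' @return Antisymmetric matrix.
#' @export
lambda_matrix <- function(n_modes) {
  z <- matrix(0, n_modes, n_modes)
  rbind(cbind(z, diag(n_modes)), cbind(-diag(n_modes), z))
}

#' @rdname lambda_matrix
#' @export
omega_matrix <- function() matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE)

## Central finite-difference gradients of a symbol's evaluate(); used by tests
## and as the generic fallback for symbols without closed-form gradients.
fd_gradient <- function(symbol, point, wrt = c("r", "p"), h = 1e-4) {
  wrt <- match.arg(wrt)
  lapply(seq_along(point[[wrt]]), function(j) {
    up <- point; dn <- point
    up[[wrt]][j] <- up[[wrt]][j] + h
    dn[[wrt]][j] <- dn[[wrt]][j] - h
    (symbol$evaluate(up) - symbol$evaluate(dn)) / (2 * h)
  })
}

#' @export
print.qcl_symbol <- function(x, ...) {
  cat(sprintf("<qcl_symbol> %d-level subsystem, %d classical mode(s)\n",
              x$n, x$n_modes))
  invisible(x)
}

#' @export
print.qcl_subsystem <- function(x, ...) {
  cat(sprintf("<qcl_subsystem> n = %d\n", x$n))
  invisible(x)
}

#' @export
print.qcl_bank <- function(x, ...) {
  cat(sprintf("<qcl_bank> kind = %s, %d mode(s), omega in [%g, %g]\n",
              x$kind, x$n_modes, min(x$omega), max(x$omega)))
  invisible(x)
}
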