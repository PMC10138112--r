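## Wigner thermal statistics of harmonic modes.
##
## The thermal mixed Weyl symbol of a harmonic mode of frequency omega at
## inverse temperature beta is the Gaussian
##   W_beta(R, P) = tanh(beta omega / 2) / pi *
##                  exp[-(2 tanh(beta omega / 2) / omega) (P^2/2 + omega^2 R^2/2)]
## normalized to unit integral over (R, P).  The effective inverse temperature
##   beta(I) = 2 tanh(beta omega / 2) / omega
## is the Nose-Hoover target that makes classical-looking dynamics reproduce
## these quantum variances, including zero-point motion at beta = Inf.

#' Thermal regime specification
#'
#' @param beta Physical inverse temperature (`k_B = 1`); `Inf` selects the
#'   zero-temperature (pure zero-point) limit.
#' @param regime `"thermal_wigner"` (quantum variances, the default),
#'   `"classical"` (Maxwell-Boltzmann variances `1/beta`), or `"zero_point"`
#'   (alias for `beta = Inf` thermal_wigner).
#' @return Object of class `qcl_thermal`.
#' @export
thermal_spec <- function(beta = Inf,
                         regime = c("thermal_wigner", "classical", "zero_point")) {
  regime <- match.arg(regime)
  if (regime == "zero_point") beta <- Inf
  if (!is.infinite(beta) && (!is.finite(beta) || beta <= 0))
    stop("'beta' must be positive (or Inf for the zero-point limit)")
  if (regime == "classical" && is.infinite(beta))
    stop("classical regime requires finite beta")
  structure(list(beta = beta, regime = regime), class = "qcl_thermal")
}

#' Effective inverse temperature of a quantized harmonic mode
#'
#' `beta_eff = 2 tanh(beta * omega / 2) / omega`.  In the classical limit
#' (`beta * omega -> 0`) this tends to `beta`; at `beta = Inf` it is
#' `2 / omega`, encoding the zero-point energy `omega / 2`.
#'
#' @param beta Inverse temperature, positive or `Inf`.
#' @param omega Mode frequency, positive.
#' @return Effective inverse temperature (vectorized over `omega`).
#' @examples
#' effective_beta(Inf, 2)   # 1
#' effective_beta(1, 2)     # tanh(1)
#' @export
effective_beta <- function(beta, omega) {
  omega <- as.numeric(omega)
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("'omega' must be positive and finite")
  if (is.infinite(beta)) return(2 / omega)
  if (!is.finite(beta) || beta <= 0) stop("'beta' must be positive or Inf")
  2 * tanh(beta * omega / 2) / omega
}

#' Wigner (or classical) variances of a thermal harmonic mode
#'
#' For the thermal Wigner distribution: `var_p = omega / (2 tanh(beta omega/2))`
#' (i.e. `1/effective_beta`) and `var_r = var_p / omega^2`.  In the classical
#' regime both follow from equipartition: `var_p = 1/beta`,
#' `var_r = 1/(beta omega^2)`.
#'
#' @param beta Inverse temperature (or a [thermal_spec()]).
#' @param omega Mode frequency.
#' @return List with numeric fields `var_r` and `var_p` (vectorized over
#'   `omega`).
#' @export
wigner_thermal_moments <- function(beta, omega) {
  if (inherits(beta, "qcl_thermal")) {
    th <- beta
    if (th$regime == "classical")
      return(list(var_r = 1 / (th$beta * omega^2), var_p = rep(1 / th$beta, length(omega))))
    beta <- th$beta
  }
  var_p <- 1 / effective_beta(beta, omega)
  list(var_r = var_p / omega^2, var_p = var_p)
}

#' Sample Wigner initial conditions for the mode banks
#'
#' Draws `(R, P)` per mode from the zero-mean Gaussians with variances given
#' by [wigner_thermal_moments()]; Nose-Hoover chain variables are initialized
#' to exactly zero (the extended-space statistical symbol carries delta
#' functions on them).  The same seed reproduces the ensemble bit for bit.
#'
#' @param phonons,em Optional [oscillator_bank()]s; at least one required.
#' @param thermal A [thermal_spec()].
#' @param n_samples Number of ensemble members.
#' @param seed Integer master seed.
#' @param w_s Optional subsystem density matrix (Hermitian, unit trace,
#'   positive semidefinite) attached to the ensemble; defaults to `NULL`
#'   (solvers fall back to the ground state of their subsystem).
#' @return Object of class `qcl_ensemble`: matrices `r`, `p` of dimension
#'   `n_samples x n_modes`, the thermal spec, seed, and metadata.
#' @examples
#' ens <- sample_initial_conditions(oscillator_bank("phonon", 1),
#'                                  thermal = thermal_spec(beta = 1),
#'                                  n_samples = 100, seed = 7)
#' @export
sample_initial_conditions <- function(phonons = NULL, em = NULL, thermal,
                                      n_samples, seed, w_s = NULL) {
  stopifnot(inherits(thermal, "qcl_thermal"))
  if (is.null(phonons) && is.null(em)) stop("at least one bank is required")
  n_samples <- as.integer(n_samples)
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  bv <- bank_vectors(phonons, em)
  mom <- wigner_thermal_moments(thermal, bv$omega)
  if (!is.null(w_s)) validate_density_matrix(w_s)
  nm <- length(bv$omega)
  set.seed(as.integer(seed))
  ## column-by-column so the stream layout is documented and stable
  r <- matrix(0, n_samples, nm)
  p <- matrix(0, n_samples, nm)
  for (j in seq_len(nm)) {
    r[, j] <- rnorm(n_samples, sd = sqrt(mom$var_r[j]))
    p[, j] <- rnorm(n_samples, sd = sqrt(mom$var_p[j]))
  }
  structure(list(r = r, p = p, n_samples = n_samples, n_modes = nm,
                 omega = bv$omega, coupling = bv$coupling,
                 which_op = bv$which_op,
                 thermal = thermal, seed = as.integer(seed), w_s = w_s,
                 eta = NULL, p_eta = NULL, time = 0),
            class = "qcl_ensemble")
}

validate_density_matrix <- function(w, tol = 1e-10) {
  w <- as_complex_matrix(w, "w_s")
  if (!is_hermitian(w, tol)) stop("'w_s' must be Hermitian")
  if (abs(sum(diag(w)) - 1) > tol) stop("'w_s' must have unit trace")
  ev <- eigen(hermitize(w), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stop("'w_s' must be positive semidefinite")
  w
}

#' Density of the per-mode thermal Wigner distribution
#'
#' Unit-normalized Gaussian density in `(R, P)` with the variances of
#' [wigner_thermal_moments()]; exposed for normalization and goodness-of-fit
#' checks.
#'
#' @param r,p Coordinates and momenta.
#' @inheritParams wigner_thermal_moments
#' @return Density values.
#' @export
wigner_thermal_density <- function(r, p, beta, omega) {
  mom <- wigner_thermal_moments(beta, omega)
  dnorm(r, sd = sqrt(mom$var_r)) * dnorm(p, sd = sqrt(mom$var_p))
}

#' @export
print.qcl_ensemble <- function(x, ...) {
  cat(sprintf("<qcl_ensemble> %d member(s), %d mode(s), time = %g\n",
              x$n_samples, x$n_modes, x$time))
  invisible(x)
}
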