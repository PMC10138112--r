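## Quantum-classical averages, correlation functions and response spectra.
##
## An average is the trace functional  <O(t)> = Tr' int dX W(X) O(X, t):
## quadrature over the lattice for grid states, an importance-weighted
## ensemble mean for trajectory solutions.

#' Observable specification
#'
#' `O(X) = matrix_part + classical_part(R, P) * Id`; the classical part is an
#' optional scalar function of the phase point.
#'
#' @param matrix_part Hermitian matrix (default zero of dimension `n`).
#' @param classical_part Optional function `f(r, p)` of the coordinate and
#'   momentum vectors, returning a scalar (vectorized over members where
#'   possible).
#' @param n Subsystem dimension when `matrix_part` is omitted.
#' @return Object of class `qcl_observable`.
#' @export
observable_spec <- function(matrix_part = NULL, classical_part = NULL, n = 2) {
  if (is.null(matrix_part)) matrix_part <- matrix(0 + 0i, n, n)
  matrix_part <- as_complex_matrix(matrix_part, "matrix_part")
  if (!is_hermitian(matrix_part)) stop("'matrix_part' must be Hermitian")
  if (!is.null(classical_part) && !is.function(classical_part))
    stop("'classical_part' must be a function of (r, p)")
  structure(list(matrix_part = matrix_part, classical_part = classical_part,
                 n = nrow(matrix_part)),
            class = "qcl_observable")
}

#' Quantum-classical average
#'
#' For a [grid_state()] holding a statistical symbol: lattice quadrature of
#' `Tr(W O)` (the observable's classical part multiplies the identity).  For
#' a trajectory solution ([sstp_propagate()]): the stratified ensemble
#' estimator at a recorded time.  Rejects unnormalized statistical symbols.
#'
#' @param x A `qcl_grid_state` or `qcl_sstp` object.
#' @param obs An [observable_spec()].
#' @param t For trajectory solutions: the recorded time (matched to the
#'   nearest snapshot); ignored for grid states.
#' @param norm_tol Allowed deviation of the trace functional from 1.
#' @return For grids: a number.  For ensembles: list with `value` and the
#'   Monte-Carlo standard error `se`.
#' @export
qc_average <- function(x, obs, t = NULL, norm_tol = 1e-4) {
  UseMethod("qc_average")
}

#' @export
qc_average.qcl_grid_state <- function(x, obs, t = NULL, norm_tol = 1e-4) {
  stopifnot(inherits(obs, "qcl_observable"))
  nrm <- trace_functional(x)
  if (abs(nrm - 1) > norm_tol)
    stop(sprintf("state is not normalized: trace functional = %.8g", nrm))
  hr <- diff(x$r_grid[1:2]); hp <- diff(x$p_grid[1:2])
  n <- x$n
  acc <- 0
  for (a in seq_len(n)) for (b in seq_len(n))
    if (obs$matrix_part[b, a] != 0)
      acc <- acc + sum(x$rho[a, b, , ]) * obs$matrix_part[b, a]
  if (!is.null(obs$classical_part)) {
    f <- outer(x$r_grid, x$p_grid, obs$classical_part)
    acc <- acc + sum(trace_field(x) * f)
  }
  Re(acc) * hr * hp
}

## Per-member estimator pieces shared by averages and correlations: the
## "left matrix" L (w_s for averages, O2 %*% w_s for correlations) expressed
## in the initial adiabatic basis, element (b0, a0).
sstp_left_elements <- function(sol, left_matrix_fun) {
  b0 <- sol$b0; a0 <- sol$a0
  v <- sol$basis0
  N <- sol$n_samples
  ## adiabatic element (i, j) of a fixed 2x2 matrix M at the initial basis:
  ## conj(v_i)^T M v_j, vectorized over members
  el <- function(M, i, j) {
    vi1 <- ifelse(i == 1L, v$v11, v$v12); vi2 <- ifelse(i == 1L, v$v21, v$v22)
    vj1 <- ifelse(j == 1L, v$v11, v$v12); vj2 <- ifelse(j == 1L, v$v21, v$v22)
    Conj(vi1) * (M[1, 1] * vj1 + M[1, 2] * vj2) +
      Conj(vi2) * (M[2, 1] * vj1 + M[2, 2] * vj2)
  }
  left_matrix_fun(el, b0, a0)
}

sstp_snapshot_index <- function(sol, t) {
  it <- which.min(abs(sol$times - t))
  if (abs(sol$times[it] - t) > 1e-9 + 1e-6 * max(abs(t), 1))
    warning(sprintf("no snapshot at t = %g; using nearest t = %g",
                    t, sol$times[it]))
  it
}

## Adiabatic matrix element O_{a_t b_t}(X_t) per member plus classical part.
sstp_obs_elements <- function(sol, obs, snap) {
  ad <- adiabatic_batch2(sol$symbol, snap$r)
  M <- obs$matrix_part
  i <- snap$a; j <- snap$b
  vi1 <- ifelse(i == 1L, ad$v11, ad$v12); vi2 <- ifelse(i == 1L, ad$v21, ad$v22)
  vj1 <- ifelse(j == 1L, ad$v11, ad$v12); vj2 <- ifelse(j == 1L, ad$v21, ad$v22)
  oel <- Conj(vi1) * (M[1, 1] * vj1 + M[1, 2] * vj2) +
         Conj(vi2) * (M[2, 1] * vj1 + M[2, 2] * vj2)
  if (!is.null(obs$classical_part)) {
    f <- obs$classical_part(snap$r, snap$p)
    oel <- oel + ifelse(i == j, f, 0)
  }
  oel
}

#' @export
qc_average.qcl_sstp <- function(x, obs, t = NULL, norm_tol = 1e-4) {
  stopifnot(inherits(obs, "qcl_observable"))
  if (is.null(t)) t <- x$times[length(x$times)]
  it <- sstp_snapshot_index(x, t)
  snap <- x$snapshots[[it]]
  left <- sstp_left_elements(x, function(el, b0, a0) el(x$w_s, b0, a0))
  oel <- sstp_obs_elements(x, obs, snap)
  contrib <- (x$n^2) * Re(left * snap$amp * oel)
  list(value = mean(contrib), se = sd(contrib) / sqrt(length(contrib)))
}

#' Time series of a quantum-classical average along a trajectory solution
#'
#' @param sol A `qcl_sstp` solution.
#' @param obs An [observable_spec()].
#' @return Data frame with columns `time`, `value`, `se`.
#' @export
qc_average_series <- function(sol, obs) {
  stopifnot(inherits(sol, "qcl_sstp"))
  left <- sstp_left_elements(sol, function(el, b0, a0) el(sol$w_s, b0, a0))
  out <- lapply(seq_along(sol$times), function(it) {
    oel <- sstp_obs_elements(sol, obs, sol$snapshots[[it]])
    contrib <- (sol$n^2) * Re(left * sol$snapshots[[it]]$amp * oel)
    c(mean(contrib), sd(contrib) / sqrt(length(contrib)))
  })
  out <- do.call(rbind, out)
  data.frame(time = sol$times, value = out[, 1], se = out[, 2])
}

#' Quantum-classical correlation function
#'
#' `C(t) = Tr' int dX W(X) O1(X, t) O2(X)` with the literal operator order
#' (the evolved `O1` left-multiplies `O2`); complex-valued in general.
#' Computed from a trajectory solution: `O1` is evolved along the members
#' (Heisenberg), `O2` and the statistical symbol are evaluated at `t = 0`.
#'
#' @param sol A `qcl_sstp` solution (evolving `O1`).
#' @param obs1,obs2 [observable_spec()]s; `obs1` must match the evolved pair
#'   bookkeeping, `obs2` enters at time zero.
#' @param times Times at which to evaluate (default all snapshots).
#' @return Data frame with columns `time`, `re`, `im`, `se`.
#' @export
qc_correlation <- function(sol, obs1, obs2, times = NULL) {
  stopifnot(inherits(sol, "qcl_sstp"), inherits(obs1, "qcl_observable"),
            inherits(obs2, "qcl_observable"))
  if (obs1$n != sol$n || obs2$n != sol$n)
    stop("observable dimensions do not match the subsystem")
  if (is.null(times)) times <- sol$times
  o2w <- obs2$matrix_part %*% sol$w_s
  left <- sstp_left_elements(sol, function(el, b0, a0) el(o2w, b0, a0))
  if (!is.null(obs2$classical_part)) {
    snap0 <- sol$snapshots[[1]]
    f0 <- obs2$classical_part(snap0$r, snap0$p)
    leftw <- sstp_left_elements(sol, function(el, b0, a0) el(sol$w_s, b0, a0))
    left <- left + f0 * leftw
  }
  out <- lapply(times, function(t) {
    it <- sstp_snapshot_index(sol, t)
    oel <- sstp_obs_elements(sol, obs1, sol$snapshots[[it]])
    contrib <- (sol$n^2) * left * sol$snapshots[[it]]$amp * oel
    c(mean(Re(contrib)), mean(Im(contrib)),
      sd(Mod(contrib)) / sqrt(length(contrib)))
  })
  out <- do.call(rbind, out)
  data.frame(time = times, re = out[, 1], im = out[, 2], se = out[, 3])
}

#' Response spectrum of a correlation function
#'
#' Windowed discrete Fourier transform of a complex correlation series on a
#' uniform time grid; returns the two-sided spectrum with the frequency grid,
#' the window recorded in the result, and the dominant peak.
#'
#' @param correlation Complex vector `C(t_k)` (or data frame with `re`/`im`).
#' @param time_grid Uniform time grid of the same length.
#' @param window `"hann"` or `"none"`.
#' @return List with `omega`, `spectrum` (complex), `power`, `peak_omega`,
#'   `window`, `domega`.
#' @export
response_spectrum <- function(correlation, time_grid, window = c("hann", "none")) {
  window <- match.arg(window)
  if (is.data.frame(correlation))
    correlation <- complex(real = correlation$re, imaginary = correlation$im)
  m <- length(correlation)
  if (length(time_grid) != m) stop("correlation and time grid lengths differ")
  dtg <- diff(time_grid)
  if (m < 4 || max(abs(dtg - dtg[1])) > 1e-9 * abs(dtg[1]))
    stop("'time_grid' must be uniform")
  wfun <- if (window == "hann") 0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))
          else rep(1, m)
  ft <- fft(correlation * wfun) * dtg[1]
  omega <- 2 * pi * (seq_len(m) - 1) / (m * dtg[1])
  omega[omega >= pi / dtg[1]] <- omega[omega >= pi / dtg[1]] - 2 * pi / dtg[1]
  ord <- order(omega)
  pw <- Mod(ft)^2
  list(omega = omega[ord], spectrum = ft[ord], power = pw[ord],
       peak_omega = omega[ord][which.max(pw[ord])],
       window = window, domega = 2 * pi / (m * dtg[1]))
}
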