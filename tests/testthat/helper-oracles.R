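## Independent numerically exact references used to validate the solvers.

## Exact coherence of the pure-dephasing model with one *quantized* mode:
## H = (eps/2) sigma_z + omega(n + 1/2) - C sigma_z x_hat, initial state
## w_s (x) thermal oscillator.  Dense truncated-Fock evolution, built from
## ladder operators only (independent of the phase-space solvers).
fock_dephasing_oracle <- function(eps, omega, coupling, beta, w_s, n_fock = 30) {
  a <- matrix(0, n_fock, n_fock)
  a[cbind(seq_len(n_fock - 1), 2:n_fock)] <- sqrt(seq_len(n_fock - 1))
  num <- t(a) %*% a
  xop <- (a + t(a)) / sqrt(2 * omega)
  H <- kronecker(eps / 2 * sigma_z, diag(n_fock)) +
    kronecker(diag(2), omega * (num + diag(n_fock) / 2)) -
    coupling * kronecker(sigma_z, xop)
  pops <- exp(-beta * omega * (0:(n_fock - 1)))
  rho_osc <- diag(pops / sum(pops))
  rho0 <- kronecker(w_s, rho_osc)
  es <- eigen(H, symmetric = TRUE)
  function(t) {   # Tr_osc of the (1,2) block of rho(t)
    ph <- exp(-1i * es$values * t)
    U <- es$vectors %*% (ph * Conj(t(es$vectors)))
    rt <- U %*% rho0 %*% Conj(t(U))
    sum(diag(rt[seq_len(n_fock), n_fock + seq_len(n_fock)]))
  }
}

## Independent evaluation of tanh through its exponential definition,
## used to pin the effective-temperature values.
tanh_oracle <- function(x) (exp(2 * x) - 1) / (exp(2 * x) + 1)
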