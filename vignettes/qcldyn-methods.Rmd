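---
title: "Mixed quantum-classical dynamics with zero-point-preserving thermostats: models and methods"
author: "qcldyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed quantum-classical dynamics with zero-point-preserving thermostats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcldyn)
```

## The model

`qcldyn` simulates an $n$-level quantum subsystem coupled bilinearly to banks
of classical harmonic modes.  Two banks are distinguished by the subsystem
operator they couple to: a "phonon" bank (conformational/vibrational
degrees of freedom, coupling operator $\hat\chi$) and an
"electromagnetic-field" bank (abstract cavity-like field modes, coupling
operator $\hat\zeta$).  Structurally the two banks are identical harmonic
banks, so one implementation serves both.  In units
$\hbar = k_B = m = 1$ the mixed Weyl symbol of the Hamiltonian is

$$
\tilde H(X, Y) \;=\; \hat H_S
+ \sum_J \Big(\tfrac{P_J^2}{2} + \tfrac{\omega_J^2 R_J^2}{2}\Big)\,\mathrm{Id}
+ \sum_K \Big(\tfrac{\Pi_K^2}{2} + \tfrac{\omega_K^2 Q_K^2}{2}\Big)\,\mathrm{Id}
- \sum_J C_J R_J \,\hat\chi \;-\; \sum_K F_K Q_K \,\hat\zeta ,
$$

a Hermitian-matrix-valued function of the classical phase point.  A *mixed
Weyl symbol* is what the partial Wigner transform of an operator over the
heavy (classical) coordinates produces: a matrix in the residual quantum
space whose entries depend on $(R, P)$.  The package represents this as a
`qcl_symbol` with callable `evaluate`, `gradient_r`, `gradient_p` fields plus
the model pieces, assembled by `assemble_hamiltonian()` from a
`subsystem_spec()` and one or two `oscillator_bank()`s.

The units convention ($\hbar = k_B = 1$, unit mode masses, kinetic terms
$P^2/2$) is the package's choice; all frequencies and energies are
dimensionless in these units and the subsystem Hamiltonian is
time-independent on the tested paths.

## The quantum-classical bracket

Dynamics of a symbol $\tilde O$ follows the quantum-classical bracket: a
commutator plus two Poisson-bracket terms,

$$
\partial_t \tilde O = \tfrac{i}{\hbar}\,[\tilde H, \tilde O]
 - \tfrac12\big(\tilde H \overleftarrow\nabla\,\Lambda\,\overrightarrow\nabla \tilde O
 - \tilde O \overleftarrow\nabla\,\Lambda\,\overrightarrow\nabla \tilde H\big),
$$

where $\Lambda$ is the antisymmetric symplectic pairing of coordinates and
momenta (`lambda_matrix()`; the commutator's antisymmetric pairing is
`omega_matrix()`).  This is a quasi-Lie bracket: it violates the Jacobi
identity, which is the price of evolving quantum and classical degrees of
freedom on the same footing.  The equation above is the Heisenberg form for
observables; the statistical symbol $\tilde W$ evolves with the opposite
sign, and averages are trace functionals
$\langle \tilde O(t)\rangle = \mathrm{Tr}'\!\int\! dX\, \tilde W(X)\,\tilde O(X,t)$.

Two solvers are provided, deliberately redundant so that each validates the
other:

* **Grid solver** (`propagate_grid()`): the reference.  The symbol is a
  matrix field on a rectangular $(R, P)$ lattice; phase-space derivatives
  use 4th-order central differences, time stepping is RK4 with node-wise
  re-Hermitization.  It is exact (up to discretization) but limited to one
  classical mode and small $n$.
* **Trajectory solver** (`sstp_propagate()`): sequential short-time
  propagation in the adiabatic basis.  Each ensemble member carries a pair
  of adiabatic indices $(a, b)$ for the evolving matrix element, moves on
  the mean surface $(E_a + E_b)/2$, and accumulates the phase
  $\exp(+i\!\int\!\omega_{ab}\,dt)$.  Nonadiabatic transitions of either
  index are sampled from $\mathbf P\cdot\mathbf d_{ab}$ with momentum-jump
  energy adjustment and importance weights.

## Numerical choices that matter

**Grid boundaries.** Finite differences use zero ghost nodes, appropriate
for decaying statistical symbols.  Central differences with such boundaries
support a weakly growing edge mode over $10^3$--$10^4$ steps; a 4-cell
absorbing layer (quadratic ramp, default rate 10) suppresses it.  The layer
only touches cells where a well-resolved state carries $\lesssim 10^{-8}$
mass; grids are sized at 6--8 thermal widths so the layer sits outside the
state's support.  Consequences: the identity observable's bracket vanishes
identically only away from the 2-cell border, and Heisenberg evolution of
spatially uniform observables is accurate only while the boundary artifact
(advected inward at $\sim P_{\max}$) stays in the low-mass region.  Time
steps are rejected above the advective stability bound
$0.6\,\min(h_R/P_{\max},\, h_P/F_{\max})$ (`grid_cfl_limit()`).

**Adiabatic bookkeeping.** The instantaneous eigenbasis is fixed by an
ascending-energy order and a deterministic phase (largest-magnitude
component real positive).  Two corrections are essential along trajectories:
(i) *trivial-crossing tracking* — when diabatic surfaces cross (overlap of
like-ordered eigenvectors below $1/2$ across a step), member indices are
relabelled to follow the physical state; (ii) *parallel transport* — any
residual phase/sign jump of the fresh convention is folded into the member
amplitude, so matrix elements evaluated in the fresh basis at any time
remain consistent.  Without either, pure-dephasing and spin-boson
cross-checks fail at the percent level or worse.

**Transitions.** The per-step transition probability is
$g/(1+g)$ with $g = |\Delta t\,\mathbf P\cdot\mathbf d|$; accepted hops
reweight by $\Delta t\,\mathbf P\cdot\mathbf d / \pi$ and shift the momentum
along $\hat{\mathbf d}$ to conserve the extended energy on the mean surface.
Upward hops with insufficient kinetic energy are *frustrated* (treated as
no-hops).  This is accurate when the bath kinetic energy exceeds the
adiabatic gap; at $k_BT \lesssim$ gap a large fraction of upward attempts is
frustrated and the ensemble visibly under-damps.  The packaged
cross-validation benchmark therefore sits in the scheme's design regime:
$\hat H_S = (\Omega/2)\sigma_x$ with $\Omega = 0.8$, one mode $\omega = 1$,
$C = 0.1$ (reorganization energy $C^2/2\omega^2 = 0.005 \ll \Omega$),
thermal Wigner sampling at $\beta = 0.15$, $N = 10^4$ members, $\Delta t =
10^{-2}$, $t \le 6$.  Weights grow roughly like
$\exp(\int |\mathbf P\cdot\mathbf d|\,dt)$; members whose weight magnitude
passes `weight_cutoff` (default 150) are frozen and counted — a documented
variance-control measure.

**Estimator.** Initial conditions are drawn once; members are assigned
initial index pairs stratified over all $n^2$ pairs.  The average is
$\langle \tilde O(t)\rangle \approx \tfrac{n^2}{N}\sum_m
\mathrm{Re}\big[ (\hat w_S)_{b_0 a_0}(X_0^m)\, \mathrm{amp}_m(t)\,
O_{a_t b_t}(X_t^m)\big]$, with all matrix elements in the (transported)
adiabatic bases.  Correlation functions replace $\hat w_S$ by
$\tilde O_2 \hat w_S$ at $t = 0$ and keep the literal operator order; no
Kubo symmetrization is applied unless the user builds it.

## Thermal and zero-point statistics

The thermal Wigner function of a harmonic mode is a Gaussian whose momentum
variance is $\mathrm{var}(P) = \omega / (2\tanh(\beta\omega/2))$, i.e. the
inverse of the *effective inverse temperature*

$$
\beta(I) = \frac{2\tanh(\beta\omega_I/2)}{\omega_I},
$$

which tends to $\beta$ classically ($\beta\omega \to 0$) and to $2/\omega$
at $T = 0$, where the variance encodes the zero-point energy $\omega/2$.
The per-mode density is normalized to unit integral (prefactor
$\tanh(\beta\omega/2)/\pi$), which is forced by its role as a probability
weight in the trace functional.  `effective_beta()`,
`wigner_thermal_moments()` and `sample_initial_conditions()` expose these;
$T = 0$ is an explicit `beta = Inf` flag rather than a large number, so
`tanh` never overflows.

## Nose-Hoover chains per mode

Each mode is thermostatted by a deterministic Nose-Hoover chain: auxiliary
pairs $(\eta_L, P_{\eta L})$, $L = 1..M$ (default $M = 2$), with feedback
$G_1 = P^2 - T(I)$ and $G_L = P_{\eta,L-1}^2/M_{\eta,L-1} - T(I)$.  The
extended energy

$$
\tilde H_e = \tilde H(X) + \sum_{I,L}\frac{P_{\eta L}^{(I)2}}{2M_{\eta L}}
+ \sum_{I,L} T^{(I)}\eta_L^{(I)}
$$

uses the standard $\tfrac12 P_\eta^2/M_\eta$ chain kinetic term — the choice
under which the antisymmetric structure matrix applied to
$\nabla_e \tilde H_e$ reproduces the textbook chain equations and
$\tilde H_e$ is exactly conserved ($\nabla H\cdot B\,\nabla H = 0$ by
antisymmetry; `nhc_structure_matrix()` builds $B$, `extended_eom()` the
flow).  The extended coordinates are ordered (all coordinates: $R_I$, then
$\eta_L^{(I)}$ mode-major; then the momenta likewise), so at rest the matrix
reduces to the block-symplectic pattern on the physical sector.  Chain
length is configurable with default 2: chains of length $>1$ are what makes
a single stiff harmonic mode ergodic.

Setting $T(I) = T$ for all modes gives classical constant-temperature
dynamics; setting $T(I) = 1/\beta(I)$ makes the same classical-looking
trajectories sample the *quantum* variances, including zero-point motion at
$\beta = \infty$.  `nhc_spec_for()` builds these targets from a symbol and a
`thermal_spec`.

Integration is the splitting NHC($dt/2$) $\to$ exact harmonic rotation($dt$)
$\to$ NHC($dt/2$), with the chain update composed through 7-point
Suzuki-Yoshida weights.  Because the harmonic stage is an exact rotation
(about the shifted centre $C\langle\chi\rangle/\omega^2$ when coupled), the
unthermostatted integrator is exact to round-off and the thermostatted
drift of $\tilde H_e$ stays near machine precision.  Chain inertial
parameters default to $M_{\eta L} = T(I)/(2\omega_I)^2$, i.e. a chain
relaxation time of half the mode period: with the more conventional
$\tau = 1/\omega$ the single-mode $P^2$ time average converges several
times slower.  A guard on $|P_\eta|$ (default $10^8$) rejects unstable time
steps instead of silently producing NaNs.  With these defaults the
long-run time average of $P^2$ for a single $\omega = 1$ mode reaches the
Wigner variances (1.0820 at $\beta = 1$; 0.5 at $\beta = \infty$) within
$\sim$0.5% by $4\times 10^6$ steps of $dt = 10^{-2}$ — the problem size the
tests and the acceptance script use.

## Exactly solvable companions

Two closed-form companions give oracle-checkable pieces:

* `bohr_frequency()` / `or_lifetime()`: the Bohr frequency
  $\omega = \Delta E/\hbar$ of a superposition and its collapse timescale
  $\tau = h/\Delta E$, with the exact identity $\omega\,\tau = 2\pi$.
* The thermo-field doubled boson: each physical mode ($a$) is paired with a
  fictitious double ($v$) under
  $H = \omega(a^\dagger a - v^\dagger v) + i\gamma(a^\dagger v^\dagger - a v)$
  (`dqmb_hamiltonian()`, truncated Fock space; the interaction string is
  read as the annihilator pair $a\,v$, the Hermiticity-consistent reading).
  From the vacuum this generates a two-mode squeezed state with
  $\langle a^\dagger a\rangle(t) = \sinh^2(\gamma t)$, independent of
  $\omega$.  The charge $a^\dagger a - v^\dagger v$ commutes with $H$ even
  after truncation, so vacuum evolution stays in the pair sector
  $|n, n\rangle$; `dqmb_mode_occupation()` propagates exactly in that
  tridiagonal sector and *monitors* truncation leakage rather than assuming
  it away.  The squeezed vacuum's number distribution is geometric with
  ratio $\tanh^2(\gamma t)$, so cutoffs must grow quickly with $\gamma t$: at
  $\gamma t = 2$ about 5% of the population lies above $n = 40$, and a
  cutoff of $\sim$500--600 is needed for $10^{-6}$ accuracy — requests that
  violate the leakage bound are rejected with a suggested cutoff.  Only a
  single mode pair is implemented; a $k$-sum is a direct product of
  independent pairs.

## What the synthetic conditions do and do not show

All inputs are generated: Gaussian Wigner samples for harmonic banks, an
Ohmic bath discretization (`ohmic_bath()`: frequencies at the quantiles of
$e^{-\omega/\omega_c}/\omega_c$, couplings
$c_j = \omega_j\sqrt{\xi\omega_c/n}$, reproducing the reorganization energy
$\xi\omega_c/2$ exactly at every $n$), and tiny matrices written in tests.
Passing tests therefore demonstrate correctness of the formalism's
implementation — conservation laws, closed-form limits, cross-validated
solvers — on *harmonic* banks with *bilinear* coupling.  They say nothing
about anharmonic environments, non-bilinear couplings, spatially resolved
fields, or any biological interpretation of the parameters; modes here are
abstract harmonic coordinates.

## Known limitations

* The grid solver handles exactly one classical mode and is practical for
  $n \le 2$; it is the reference, not the production path.
* The trajectory solver currently implements two-level subsystems (the
  batched closed-form eigensystem); its momentum-jump transitions are
  unreliable when $k_BT$ is well below the adiabatic gap (see above), and
  importance weights grow exponentially with coupling strength and time.
* Wave-function-collapse events are not part of the propagator; the
  collapse-timescale utilities are diagnostic only.
* No Kubo-transformed correlation variant is built in; the literal operator
  ordering is computed.
* Output formats are CSV/JSON (text only); ensembles regenerate exactly
  from the sidecar metadata (single RNG stream, column-major draws, seeds
  recorded).
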