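Package: qcldyn
Title: Mixed Quantum-Classical Liouville Dynamics with Thermostatted
    Harmonic Mode Banks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for an n-level quantum subsystem bilinearly coupled to
    banks of classical harmonic phonon and electromagnetic-field modes, evolved
    under the quantum-classical bracket acting on mixed Weyl symbols. Provides
    deterministic Nose-Hoover chain thermostats per mode whose target
    temperatures reproduce either classical thermal or quantum (zero-point)
    Wigner statistics, seeded Wigner sampling of initial conditions, a
    finite-difference phase-space grid reference solver, an adiabatic-basis
    trajectory solver with momentum-jump nonadiabatic transitions,
    quantum-classical averages, correlation functions and response spectra,
    and exactly solvable companion models (Bohr-frequency/superposition
    lifetime utilities and a thermo-field doubled-boson mode on a truncated
    Fock space).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
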