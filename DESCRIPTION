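Package: polhop
Title: Surface-Hopping Nonadiabatic Dynamics in a Polarizable Point-Dipole Environment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decoherence-corrected fewest-switches trajectory surface hopping
    for multi-state analytic (diabatic) electronic models embedded in a
    polarizable induced-point-dipole molecular-mechanics environment.
    Implements coupled induced-dipole electrostatics with dual exclusion-rule
    field sets solved by preconditioned conjugate gradients, linear-response
    and corrected-linear-response environment contributions to excitation
    energies, wavefunction-overlap time-derivative nonadiabatic couplings
    (determinant- and orbital-derivative routes), harmonic Wigner sampling of
    initial conditions, a file-exchange protocol for external
    electronic-structure backends, and ensemble analysis of proton-transfer
    and hydrogen-bond-breaking events with binomial confidence margins.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
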