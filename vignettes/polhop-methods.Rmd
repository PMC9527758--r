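---
title: "Surface hopping in a polarizable environment: models, conventions, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface hopping in a polarizable environment: models, conventions, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polhop)
```

polhop implements the full method stack of trajectory surface hopping with
a polarizable (induced-point-dipole) classical environment on analytic
model systems. This vignette records the models, the conventions chosen
where several are defensible, the numerical parameters and why they hold
their defaults, and what the built-in fixture does and does not emulate.

## The polarization model

Each classical site carries static multipoles (charge, dipole, traceless
quadrupole in the Buckingham convention, with the quadrupole potential
written $V = \mathbf r^{T}\Theta\,\mathbf r / (2 r^{5})$) and an isotropic
polarizability $\alpha$ (Bohr$^3$). Two static fields, $E_p$ and $E_d$,
are assembled from the same multipoles but with independent exclusion-pair
lists and scale factors — the dual-field structure of AMOEBA-style force
fields, where "group" and "scale" exclusions differ between the energy and
the induction operators. With empty lists the two fields coincide, and the
package treats the exclusion lists purely as data: pairs with a scale
factor, stored symmetrically.

The induced dipoles solve $(\alpha^{-1}-T)\mu = E$ for each field set. The
system matrix is kept dense (problem sizes here are at most a thousand
sites) and the solve is a conjugate gradient preconditioned by the
per-site polarizability, with two explicit failure modes: non-convergence
reports the residual, and a non-positive-curvature direction reports that
the polarization matrix is not positive definite (overlapping sites or
excessive polarizabilities; the cure is separation or Thole damping).
Thole exponential damping of $T$ is implemented but off by default: the
fixtures keep sites well separated, so damping is a user decision, not a
hidden one.

Conventions fixed here, since the stationarity limit admits several
equivalent writings: the polarization energy is $-\tfrac12\langle
\mu_d,E_p\rangle$; the LR environment shift of an excitation is
$-\langle\mu,E\rangle$ with both the field and the dipoles generated by
the transition density; the state-specific (cLR) correction is
$-\tfrac12\langle\mu^\Delta,E^\Delta\rangle$ from the difference density,
applied strictly a posteriori (it never feeds back into forces). The
factor difference between the LR term (no $\tfrac12$) and the
polarization/cLR terms (with $\tfrac12$) follows the corrected
linear-response literature.

## Electronic models

Diabatic models carry analytic diagonal potentials (Morse, harmonic,
exponential repulsion, constants) over interatomic distances, plus
constant or Gaussian couplings. Diagonalization gives adiabatic states;
gradients use the Hellmann–Feynman rule, which is exact for eigenvectors
of an analytic Hamiltonian. The environment couples to the diagonal: each
diabat's atomic charges interact with the static multipole potential.
Excited states additionally receive the LR shift when the environment is
polarizable. During dynamics the LR shift's gradient for the active state
is taken by central finite differences (step $10^{-3}$ Bohr) — the model
has no analytic LR gradient, and the verified cost of the approximation
is an energy drift of order $10^{-5}$ eV over tens of femtoseconds with
polarizable spectators.

Transition densities have no exact analogue in a model space, so the
package declares one and uses it consistently: each diabat carries a
vector of transition weights summing to zero, and the transition charges
between adiabatic states $I,J$ are $\sum_k U_{kI}U_{kJ}q^{tr}_k$. Phases
are fixed by making the first significant eigenvector element positive,
then tracked against the previous step during dynamics; at
near-degeneracies the tie-break is maximum overlap with the previous step
when history exists, diabatic index order otherwise.

## Overlaps and couplings

For CIS-like auxiliary wavefunctions the state overlap between steps is
computed two ways. The determinant route expands every pair of singly
substituted determinants exactly (it is the oracle, checked against an
independent permutation-sum determinant in the tests). The
orbital-derivative route keeps only products with a single substituted
orbital overlap around the diagonal reference product:
same-hole pairs contribute $D_0\,S_{ab}/S_{ii}$, same-particle pairs
$-D_0\,S_{ji}S_{aa}/(S_{ii}S_{jj})$, and doubly-off-diagonal pairs are
dropped. The truncation is first-order in the inter-step MO rotation with
second-order error, which is why the two routes agree to $10^{-4}$ under
$10^{-3}$ rotations in the acceptance checks. For the built-in models the
overlap is exactly $U(t)^TU(t+\Delta t)$.

The time-derivative coupling is the Hammes-Schiffer–Tully finite
difference $\sigma_{IJ}=(S_{IJ}-S_{JI})/(2\Delta t)$ — antisymmetric by
construction and second-order accurate, as the rotating-frame tests
verify. Sign alignment multiplies each later-step state by the sign of
its diagonal overlap; without it a stray eigenvector sign flip would
invert rows of $\sigma$. If the active state's diagonal overlap falls
below 0.5 the step is flagged as a trivial crossing.

## Dynamics protocol

The defaults mirror the standard protocol for ultrafast azine
photodynamics: nuclear step 0.5 fs; electronic TDSE substep 0.025 fs with
energies and couplings interpolated linearly across the nuclear step and
each substep applying the exact unitary exponential of the frozen
midpoint generator (the electronic norm is conserved to machine
precision); maximum 100 fs; decoherence parameter 0.1 Hartree;
termination when the S1/S0 gap drops below 0.2 eV, with that time taken
as the internal-conversion time; invalidation at 0.5 eV total-energy
drift (measured cumulatively from the start — the step-to-step reading of
that criterion is the other defensible choice) and for runs shorter than
5 fs. Within a step the precedence is drift, then gap, then the time cap.

Hopping probabilities use the fewest-switches flux form
$P_{a\to J}=\max(0,\,2\Delta t\,\sigma_{aJ}\,\mathrm{Re}(c_Jc_a^*)/|c_a|^2)$,
whose sign convention is pinned operationally by a Monte-Carlo test
against the TDSE population loss rather than by transcription. One
uniform draw per nuclear step decides the hop; each trajectory owns a
private RNG stream seeded from (global seed, trajectory index), so
ensembles are reproducible trajectory-by-trajectory. Hops are evaluated
among excited states only — recovery of the ground state is handled
entirely by the gap-termination rule, since the S1/S0 crossing region is
exactly where single-reference excited-state methods (which this package
emulates) are unreliable.

Kinetic-energy conventions are QM-only throughout: the energy available
to pay for an upward hop, the rescaling factor after an accepted hop
(one scalar on the QM velocities; any classical atoms are untouched), and
the decoherence lifetime
$\tau_J = |E_J-E_a|^{-1}(1+\alpha/K_{qm})$ all use the kinetic energy of
the QM atoms. The suite verifies by construction that adding cold (or
hot) classical atoms changes no electronic decision on a fixed path.
Frustrated hops change nothing — velocities keep their original
direction. The Berendsen rescale and the harmonic wall exist for
equilibration only; the time constant is exposed as a time (default
0.05 ps), since the reference protocol quotes "0.05 ps$^{-1}$" with
ambiguous units.

## Initial conditions

Hessians are central differences of analytic gradients (step 0.01 Bohr,
symmetrized), normal modes are computed after projecting rigid-body
generators (translations and rotations built at the reference geometry;
degenerate generators of linear systems drop out automatically via a
rank-revealing QR), and Wigner sampling draws $Q\sim N(0,1/2\omega)$,
$P\sim N(0,\omega/2)$ per mode — the harmonic vibrational ground state.
Thermal occupation is deliberately not implemented; the sampling hook
takes an explicit mode list, and imaginary frequencies in that list are
an error rather than a silent drop. Initial electronic states are drawn
with acceptance probability $f/f_{\max}$ from the pool of (geometry,
state) pairs whose vertical excitation lies within a window around the
reference energy; the "0.5 eV width" of the protocol is read as a full
width ($\pm 0.25$ eV), configurable.

## The EDPT fixture

`make_edpt_fixture()` builds a five-atom donor–H–acceptor cluster
(ring carbon, acceptor nitrogen, transferring hydrogen, donor oxygen,
second water hydrogen) with three diabats: a covalent ground state
(O–H bonded), a bright locally excited state at $\sim$5.0 eV with
oscillator strength $\sim$0.18, and a dark ion-pair charge-transfer
state at $\sim$6.5 eV vertical. The design targets, chosen once during
construction and then frozen:

* proton transfer must be a *rare* event under ground-state Wigner
  sampling, as in the reference photodynamics — the S1 barrier between
  the local-excitation minimum and the charge-transfer funnel is
  $\sim$0.3–0.4 eV, giving ensemble reactive fractions of a few percent;
* the S0/CT crossing seam sits near the product N–H well
  ($\approx 1.1$ Å), so that a transferred proton oscillates below the
  transfer detector's 1.1 Å threshold for several frames before the
  0.2 eV gap termination fires — otherwise every reactive trajectory
  would terminate mid-transfer and no detector could see it;
* weak 1–3 harmonic tethers stiffen the bending/torsional modes
  (tens-to-hundreds of cm$^{-1}$) so that Wigner sampling stays in the
  physical basin; without them four near-free modes produce unphysical
  initial geometries;
* spectator sites are single positive charges (+0.18 e, $\alpha = 7$
  Bohr$^3$, water-like) placed by minimum-distance rejection sampling in
  a shell around the donor oxygen — hydrogen-bond-donor-like sites that
  stabilize the donor lone pair and therefore *destabilize* the ion-pair
  CT state ($+0.3$–0.4 eV at three spectators) while barely moving the
  local excitation, and for which the cLR correction is negative
  (CT-stabilizing), reproducing the qualitative directions reported for
  the real cluster.

What the fixture does not emulate: real TD-DFT surfaces (no SCF, no
response equations), biradical ground-state character after transfer (the
ion-pair diabat plays that role), bonded QM/MM boundaries, bulk solvation
(spectators are a handful of fixed sites, not a droplet), and
finite-temperature sampling. Passing tests therefore demonstrate the
correctness and internal consistency of the method stack — solver
identities, conservation laws, statistical consistency, qualitative
environment physics — not quantitative agreement with any ab initio
photodynamics.

## Numerical choices

* PCG tolerance $10^{-8}$ on the residual norm (tests that compare
  against dense solves tighten it to $10^{-12}$); diagonal (per-site
  $\alpha$) preconditioner; the uncoupled guess $\mu = \alpha E$ starts
  the iteration.
* Eigen-decompositions use symmetric/Hermitian routines; adiabatic
  energies are sorted ascending and eigenvector phases fixed as above.
* The TDSE substep propagator is the exact exponential of the frozen
  interpolated generator, evaluated by Hermitian eigendecomposition: the
  norm is exact, and the only error is interpolation ($O(\Delta t_e^2)$).
* The fewest-switches probabilities are clamped at zero individually and
  normalized only if their sum exceeds one.
* Degenerate states ($|\Delta E| < 10^{-12}$) are not decoherence-damped
  (infinite lifetime) and are tie-broken deterministically.
* Problem sizes in the shipped tests and acceptance script: 50-site
  polarization solves, 4-electron/6-orbital overlap oracles, 100 fs
  single trajectories, a 60-trajectory ensemble with 96 Wigner samples,
  and $10^4$-draw Monte-Carlo checks — sizes chosen so the full suite
  runs in well under a minute per module while leaving the statistical
  checks with non-trivial power.

## Known limitations

The LR-shift gradient is finite-difference (exact gradients would need a
response formalism the models do not define); environment sites are
frozen during trajectories; hops to the ground state are disabled by
design, so ground-state recovery exists only through the gap criterion;
the orbital-derivative overlap truncation degrades for large inter-step
rotations (trivial crossings are flagged, not repaired beyond sign
alignment); and the Wald margin is a large-count approximation that
degenerates at $k = 0$ or $k = n$ (the degenerate margin is reported as
zero, matching the convention used for the published counts this package
reproduces).
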