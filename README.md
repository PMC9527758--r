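# polhop

Decoherence-corrected fewest-switches surface hopping (DC-FSSH) for
multi-state diabatic models embedded in a polarizable induced-point-dipole
(IPD) environment — a desk-scale simulator for nonadiabatic photochemistry
in polarizable surroundings, aimed at method developers and students who
want every ingredient of the polarizable-embedding surface-hopping stack
exercisable without any external quantum-chemistry code.

The flagship application built in is an electron-driven proton transfer
(EDPT): a hydrogen-bonded donor–H–acceptor chromophore (an azine–water-like
cluster) where photoexcitation of a bright local state can populate a dark
charge-transfer state that pulls the proton across the hydrogen bond.

## What it computes

**Polarizable environment.** Sites carry static charges `q`, dipoles
`μ_s`, traceless quadrupoles `Θ_s`, and isotropic polarizabilities `α`.
Two static fields `E_p`, `E_d` (differing by exclusion rules) drive two
induced-dipole sets through

    (α⁻¹ − T) μ = E,

solved by a diagonally preconditioned conjugate gradient (`T` is the
dipole interaction tensor, optionally Thole-damped). At stationarity the
polarization energy is `−½⟨μ_d, E_p⟩`. Excitation energies acquire a
linear-response (LR) shift `−⟨μ, E⟩` from the field of the transition
density, and an a-posteriori state-specific correction (corrected linear
response, cLR) `−½⟨μ^Δ, E^Δ⟩` from the ground↔excited difference density.

**Electronic states.** Analytic diabatic models (Morse/harmonic diagonal
terms, constant or Gaussian couplings, per-diabat atomic charges and
transition-charge weights) are diagonalized on the fly; gradients follow
from the Hellmann–Feynman rule. An external electronic-structure backend
can be plugged in through a formatted file exchange
(`system.xyz` out, `interface.dat` in; layout below).

**Nonadiabatic couplings.** Time-derivative couplings are estimated from
wavefunction overlaps at successive steps via the Hammes-Schiffer–Tully
finite difference

    σ_IJ = (S_IJ − S_JI) / (2Δt),

with overlaps of CIS-like auxiliary wavefunctions computed either by exact
determinant expansion (the oracle route) or the cheaper orbital-derivative
truncation, and exactly as `U(t)ᵀU(t+Δt)` for the built-in models.

**Dynamics.** Velocity Verlet (0.5 fs default) plus an electronic TDSE
integrated in 0.025 fs substeps with linearly interpolated energies and
couplings; fewest-switches hopping with one uniform draw per step;
velocity rescaling and frustrated-hop accounting that use the kinetic
energy of the QM atoms only; Granucci–Persico energy-based decoherence
(α = 0.1 Hartree); Berendsen thermostat and harmonic wall for
equilibration. Trajectories terminate when the S1/S0 gap drops below
0.2 eV (internal conversion), the total-energy drift exceeds 0.5 eV
(invalid), or 100 fs is reached; runs shorter than 5 fs are invalid.

**Initial conditions and statistics.** Numerical Hessians from analytic
gradients, normal-mode analysis, harmonic ground-state Wigner sampling,
oscillator-strength-weighted state selection inside a 0.5 eV window, and
ensemble statistics (proton-transfer and H-bond-break fractions) with
two-sigma Wald margins.

## Worked example

```r
library(polhop)

# chromophore + 3 polarizable spectator sites around the donor oxygen
fx3 <- make_edpt_fixture(n_spectators = 3, seed = 1)
res <- evaluate_states(fx3$model, fx3$R0, env = fx3$env)
res
#> electronic_result: 3 states
#>   excitations (eV): 4.964 6.829
#>   f: 0.1833 0.0033
ct_character(res$U, fx3$model$ct_labels)
#> 0.000 0.006 0.994
dq <- res$state_charges[3, ] - res$state_charges[1, ]
hartree_to_ev(clr_correction(source_charges(fx3$R0, dq, "difference"), fx3$env))
#> -0.0372

# a surface-hopping ensemble on the isolated cluster
fx <- make_edpt_fixture(0)
run_ensemble(fx, n_traj = 24, config = sh_config(seed = 11), n_wigner = 48)
#> ensemble_summary: 24 trajectories, 24 valid
#>   proton transfer: 1/24 (4.2 % +/- 8 %)
#>   H-bond break:    9/24 (38 % +/- 20 %)

fraction_with_margin(5, 222)[c("percent", "margin")]
#> $percent 2.252252   $margin 1.991661
```

The first block shows the two excited states of the embedded cluster: a
bright local excitation at 4.96 eV (oscillator strength 0.18) and a dark
state at 6.83 eV that is 99 % charge-transfer in character. The
polarizable spectator sites destabilize that ion-pair state (vs 6.50 eV
for the bare cluster), while the state-specific cLR correction pulls it
back down by 0.037 eV — the LR/SS tug-of-war that motivates a-posteriori
state-specific corrections. The ensemble block runs the full pipeline
(Hessian → Wigner → selection → DC-FSSH → event detection): proton
transfer is a rare event on this fixture, as it is in the reference
photodynamics, and the `fraction_with_margin` call is the statistic used
to quote such fractions with a two-sigma margin.

## Command line

```sh
Rscript inst/cli/polhop.R run --spectators 0 --ntraj 24 --seed 11 --out run1/
Rscript inst/cli/polhop.R analyze run1/ --donor 4 --h 3 --acceptor 2
Rscript inst/cli/polhop.R hessian --out modes.csv
Rscript inst/cli/polhop.R sample --n 16 --seed 3 --out wigner
```

`run` writes one XYZ + CSV + JSON triple per trajectory and an ensemble
summary; `analyze` recomputes event statistics from those files.

## External backend protocol

At each step the driver writes `system.xyz` (standard XYZ, Angstrom) into
the work directory and invokes the configured command, which must write
`interface.dat`:

```
nstates <N>
natoms <M>
energies
<E_1>              # Hartree, one per line, ascending
...
gradient 1
<gx gy gz>         # M lines, Hartree/Bohr
...
gradient N
...
oscillator_strengths   # optional, N-1 lines (excited states)
...
expansion              # optional, N rows of N state-expansion coefficients
...
end
```

All values are parsed at full precision; malformed files produce errors
naming the offending line, state, and atom.

## Model and MM-site configuration (JSON)

`read_model_config()` reads `{n_states, n_atoms, atoms, terms, couplings,
state_charges, trans_charges, trans_dipoles, ct_labels}` with distances
in Bohr and energies in Hartree; `read_multipole_config()` reads
`{sites: [{position (Å), charge, dipole, quadrupole, alpha (Å³)}, ...],
exclude_p, exclude_d, scale_p, scale_d, damping}`.

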