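# Built-in model system: a three-state donor--H--acceptor chromophore
# emulating an azine--water hydrogen-bonded cluster that undergoes
# electron-driven proton transfer (EDPT), surrounded by polarizable
# spectator sites. Ground (covalent), bright locally-excited (LE) and dark
# charge-transfer (CT, ion-pair) diabats; the transferring H sits between a
# donor oxygen and an acceptor ring nitrogen.

# atoms: 1 C (ring anchor), 2 N (acceptor), 3 H (transferring),
#        4 O (donor), 5 Hw (second water hydrogen)
edpt_atoms <- c("C", "N", "H", "O", "Hw")
edpt_masses_amu <- c(12.011, 14.007, 1.008, 15.999, 1.008)

edpt_geometry_guess <- function() {
  ang_to_bohr(rbind(
    c(0.00, 0.00, -1.35),   # C
    c(0.00, 0.00,  0.00),   # N
    c(0.10, 0.00,  1.90),   # H
    c(0.20, 0.00,  2.87),   # O
    c(1.10, 0.35,  3.15)))  # Hw
}

edpt_model <- function(ct_offset = 0.1675) {
  terms_common <- list(
    list(type = "harm", i = 1, j = 2, k = 0.60, r0 = 2.5511),
    list(type = "harm", i = 4, j = 5, k = 0.50, r0 = 1.8200),
    # weak 1-3 tethers stiffening bends/torsions of the cluster frame
    # (none involves the transferring H except the soft H-Hw azimuth pin)
    list(type = "harm", i = 1, j = 4, k = 0.030, r0 = 7.985),
    list(type = "harm", i = 1, j = 5, k = 0.010, r0 = 8.782),
    list(type = "harm", i = 2, j = 5, k = 0.010, r0 = 6.340),
    list(type = "harm", i = 3, j = 5, k = 0.010, r0 = 3.097))
  terms <- list(
    c(terms_common, list(                       # S0: covalent, O-H bonded
      list(type = "morse", i = 3, j = 4, D = 0.18, a = 1.2, r0 = 1.83),
      list(type = "morse", i = 2, j = 3, D = 0.008, a = 0.73, r0 = 3.59),
      list(type = "morse", i = 2, j = 4, D = 0.004, a = 0.8, r0 = 5.42))),
    c(terms_common, list(                       # LE: bright, weaker H bond
      list(type = "morse", i = 3, j = 4, D = 0.16, a = 1.2, r0 = 1.83),
      list(type = "morse", i = 2, j = 3, D = 0.004, a = 0.73, r0 = 3.59),
      list(type = "morse", i = 2, j = 4, D = 0.002, a = 0.8, r0 = 5.42),
      list(type = "const", value = 0.18375))),
    c(terms_common, list(                       # CT: ion pair, N-H bonded
      list(type = "morse", i = 2, j = 3, D = 0.06, a = 0.95, r0 = 1.95),
      list(type = "rep",   i = 3, j = 4, A = 0.5, b = 1.5),
      list(type = "morse", i = 2, j = 4, D = 0.03, a = 0.8, r0 = 5.20),
      list(type = "const", value = ct_offset))))
  couplings <- list(
    list(i = 1, j = 2, const = 0.004),
    list(i = 1, j = 3, const = 0.003),
    list(i = 2, j = 3, const = 0.0005,
         gauss = list(i = 2, j = 3, A = 0.008, r0 = 3.25, w = 0.35)))
  state_charges <- rbind(
    c( 0.15, -0.30, 0.25, -0.45, 0.35),         # S0
    c( 0.25, -0.40, 0.25, -0.45, 0.35),         # LE
    c(-0.35, -0.45, 0.35,  0.05, 0.40))         # CT: chromophore anion
  trans_charges <- rbind(
    c( 0.05, -0.10, 0.02,  0.06, -0.03),
    c( 0.30, -0.30, 0.00,  0.00,  0.00),
    c(-0.25,  0.25, 0.05, -0.05,  0.00))
  td <- array(0, c(3, 3, 3))
  td[1, 2, ] <- td[2, 1, ] <- c(1.20, 0.00, 0.30)   # bright LE
  td[1, 3, ] <- td[3, 1, ] <- c(0.03, 0.00, 0.05)   # dark CT
  td[2, 3, ] <- td[3, 2, ] <- c(0.10, 0.00, 0.10)
  diabatic_model(3, 5, terms, couplings, state_charges, trans_charges,
                 td, ct_labels = c(FALSE, FALSE, TRUE), atoms = edpt_atoms)
}

#' Build the EDPT model fixture
#'
#' Constructs the package's built-in three-state electron-driven
#' proton-transfer system: a donor--H--acceptor chromophore (ring carbon,
#' acceptor nitrogen, transferring hydrogen, donor oxygen, second water
#' hydrogen) with ground, bright locally-excited, and dark charge-transfer
#' diabats, plus `n_spectators` polarizable positively charged sites placed
#' around the donor oxygen by minimum-distance rejection sampling inside a
#' spherical shell (hydrogen-bond-donor-like sites: they stabilize the donor
#' lone pair, i.e. the covalent states, and destabilize the ion-pair CT
#' state). The chromophore geometry is relaxed on the ground adiabatic
#' surface of the isolated model, so vertical energies for different
#' `n_spectators` are comparable at the same geometry.
#'
#' @param n_spectators number of polarizable spectator sites (>= 0).
#' @param seed integer seed controlling spectator placement.
#' @param q_spec charge of each spectator site (a.u.).
#' @param alpha_spec isotropic polarizability of each spectator (Bohr^3).
#' @param shell_ang inner/outer shell radii around the donor oxygen (Angstrom).
#' @return list with elements `model` (a `diabatic_model`), `env`
#'   (`multipole_set` of spectators, or `NULL` when `n_spectators = 0`),
#'   `masses` (a.u.), `R0` (relaxed geometry, Bohr), `atoms`, and index
#'   helpers `donor`, `h`, `acceptor`.
#' @export
make_edpt_fixture <- function(n_spectators = 0, seed = 1, q_spec = 0.18,
                              alpha_spec = 7.0, shell_ang = c(2.8, 4.5)) {
  stopifnot(n_spectators >= 0)
  model <- edpt_model()
  R0 <- relax_ground_state(model, edpt_geometry_guess())
  env <- NULL
  if (n_spectators > 0) {
    set.seed(seed %% 2147483647L)
    center <- R0[4, ]
    rmin <- ang_to_bohr(shell_ang[1]); rmax <- ang_to_bohr(shell_ang[2])
    min_sep <- ang_to_bohr(2.0); min_qm <- ang_to_bohr(2.2)
    pos <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(pos) < n_spectators) {
      tries <- tries + 1L
      if (tries > 10000L * n_spectators)
        stop("spectator placement failed; widen the shell")
      u <- stats::runif(3, -1, 1)
      nu <- sqrt(sum(u * u))
      if (nu < 1e-8) next
      r <- (rmin^3 + stats::runif(1) * (rmax^3 - rmin^3))^(1 / 3)
      p <- center + r * u / nu
      if (nrow(pos) > 0 && min(sqrt(rowSums(sweep(pos, 2, p)^2))) < min_sep) next
      if (min(sqrt(rowSums(sweep(R0, 2, p)^2))) < min_qm) next
      pos <- rbind(pos, p)
    }
    env <- multipole_set(pos, charges = rep(q_spec, n_spectators),
                         alphas = rep(alpha_spec, n_spectators))
  }
  list(model = model, env = env,
       masses = amu_to_au(edpt_masses_amu), R0 = R0, atoms = edpt_atoms,
       donor = 4L, h = 3L, acceptor = 2L)
}

# relax on the ground adiabatic surface (isolated model) with BFGS
relax_ground_state <- function(model, R_init) {
  n <- model$n_atoms
  fn <- function(x) evaluate_states(model, matrix(x, n, 3))$energies[1]
  gr <- function(x) {
    res <- evaluate_states(model, matrix(x, n, 3))
    as.numeric(res$gradients[1, , ])
  }
  opt <- stats::optim(as.numeric(R_init), fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  matrix(opt$par, n, 3)
}

#' Build a harmonic test cluster
#'
#' A simple cluster of atoms harmonically tethered to lattice-like reference
#' positions, used for thermostat and confinement checks.
#'
#' @param n_atoms number of atoms.
#' @param seed placement seed.
#' @param k tether force constant (Hartree/Bohr^2).
#' @param mass_amu atomic mass (amu).
#' @return list with `R0` (Bohr), `masses` (a.u.) and `force_fn(R)` returning
#'   list(forces, energy) for the tether potential.
#' @export
make_thermal_cluster <- function(n_atoms = 16, seed = 1, k = 0.05,
                                 mass_amu = 15.999) {
  set.seed(seed %% 2147483647L)
  R0 <- matrix(stats::rnorm(n_atoms * 3, sd = ang_to_bohr(2.0)), n_atoms, 3)
  force_fn <- function(R) {
    d <- R - R0
    list(forces = -k * d, energy = 0.5 * k * sum(d * d))
  }
  list(R0 = R0, masses = rep(amu_to_au(mass_amu), n_atoms), force_fn = force_fn)
}
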