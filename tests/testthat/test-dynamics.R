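# Propagation machinery: Verlet, TDSE, hopping, decoherence, thermostat,
# wall, termination rules, and full trajectories.

test_that("velocity Verlet: free particle and harmonic-oscillator energy", {
  R <- matrix(0, 1, 3); v <- matrix(c(0.001, 0, 0), 1, 3)
  free <- verlet_step(R, v, 1836, matrix(0, 1, 3),
                      function(Rn) matrix(0, 1, 3), fs_to_au(0.5))
  expect_equal(free$R, v * fs_to_au(0.5), tolerance = 1e-14)
  expect_equal(free$v, v)

  # 1D oscillator, ~500 cm^-1: integrate one period at 0.5 fs
  k <- 0.0095; mass <- 1837.4
  force <- function(Rn) -k * Rn
  energy <- function(R, v) 0.5 * k * sum(R^2) + 0.5 * mass * sum(v * v)
  period <- 2 * pi * sqrt(mass / k)
  dt <- fs_to_au(0.5)
  run_osc <- function(dt) {
    R <- matrix(c(0.2, 0, 0), 1, 3); v <- matrix(0, 1, 3)
    f <- force(R); e0 <- energy(R, v)
    drift <- 0
    for (s in seq_len(ceiling(period / dt))) {
      st <- verlet_step(R, v, mass, f, force, dt)
      R <- st$R; v <- st$v; f <- st$forces
      drift <- max(drift, abs(energy(R, v) - e0))
    }
    drift
  }
  d1 <- run_osc(dt)
  expect_lt(d1, 1e-6)
  d2 <- run_osc(dt / 2)
  expect_gt(d1 / d2, 3)  # ~4x second-order improvement
  expect_lt(d1 / d2, 6)
})

test_that("TDSE propagation: decoupled limit and Rabi rotation", {
  cvec <- c(1 + 0i, 0i)
  E <- c(0.1, 0.3)
  sig0 <- matrix(0, 2, 2)
  out <- propagate_tdse(cvec, E, E, sig0, sig0, fs_to_au(0.5), fs_to_au(0.025))
  expect_equal(Mod(out), Mod(cvec), tolerance = 1e-12)
  expect_equal(Arg(out[1]), Arg(exp(-1i * E[1] * fs_to_au(0.5))),
               tolerance = 1e-10)

  # degenerate energies, constant coupling: populations follow cos^2/sin^2
  sig <- matrix(c(0, -0.004, 0.004, 0), 2, 2)
  cvec <- c(1 + 0i, 0i)
  t_tot <- fs_to_au(10)
  n_step <- 20
  for (s in seq_len(n_step))
    cvec <- propagate_tdse(cvec, c(0.2, 0.2), c(0.2, 0.2), sig, sig,
                           t_tot / n_step, t_tot / n_step / 20)
  expect_equal(Mod(cvec[1])^2, cos(0.004 * t_tot)^2, tolerance = 1e-8)
  expect_equal(Mod(cvec[2])^2, sin(0.004 * t_tot)^2, tolerance = 1e-8)
  expect_error(propagate_tdse(cvec, c(NA, 1), c(0, 1), sig, sig, 1, 0.5),
               "non-finite")
})

test_that("TDSE matches an adaptive dense-integrator oracle on 4 states", {
  skip_if_not_installed("deSolve")
  set.seed(19)
  n <- 4
  E0 <- sort(runif(n, 0, 0.3)); E1 <- E0 + rnorm(n, sd = 0.01)
  A0 <- matrix(rnorm(n * n, sd = 0.003), n, n); s0 <- A0 - t(A0)
  A1 <- matrix(rnorm(n * n, sd = 0.003), n, n); s1 <- A1 - t(A1)
  c0 <- complex(real = rnorm(n), imaginary = rnorm(n))
  c0 <- c0 / sqrt(sum(Mod(c0)^2))
  dt <- fs_to_au(0.5)
  got <- propagate_tdse(c0, E0, E1, s0, s1, dt, fs_to_au(0.00025))
  deriv <- function(t, y, parms) {
    cc <- complex(real = y[1:n], imaginary = y[(n + 1):(2 * n)])
    th <- t / dt
    E <- (1 - th) * E0 + th * E1
    s <- (1 - th) * s0 + th * s1
    dc <- -1i * E * cc - s %*% cc
    list(c(Re(dc), Im(dc)))
  }
  sol <- deSolve::ode(c(Re(c0), Im(c0)), c(0, dt), deriv, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-12)
  ref <- complex(real = sol[2, 2:(n + 1)], imaginary = sol[2, (n + 2):(2 * n + 1)])
  expect_lt(max(Mod(got - ref)), 1e-8)
  expect_equal(sum(Mod(got)^2), 1, tolerance = 1e-10)
})

test_that("hop probabilities: zeros, clamping, and the flux sign convention", {
  cvec <- c(sqrt(0.7) + 0i, sqrt(0.3) + 0i)
  expect_equal(hop_probabilities(cvec, matrix(0, 2, 2), 20, 1), c(0, 0))
  # population flowing INTO the active state: clamped to zero
  sig_in <- matrix(c(0, 0.01, -0.01, 0), 2, 2)  # sigma[1,2] < 0
  p <- hop_probabilities(cvec, sig_in, 20, 1)
  expect_equal(p, c(0, 0))
  # opposite sign: positive probability out of the active state
  p2 <- hop_probabilities(cvec, -sig_in, 20, 1)
  expect_gt(p2[2], 0)
  expect_warning(hop_probabilities(c(0i, 1 + 0i), -sig_in, 20, 1), "below")
})

test_that("hop frequency reproduces the TDSE population flux (Monte Carlo)", {
  # frozen two-state segment with weak constant coupling: compare the
  # ensemble hop frequency over one step with -d|c_a|^2/|c_a|^2 of the TDSE
  sig <- matrix(c(0, -4e-4, 4e-4, 0), 2, 2)
  E <- c(0.0, 0.05)
  cvec <- c(sqrt(0.8) + 0i, sqrt(0.2) * exp(0.3i))
  dt <- fs_to_au(0.5)
  c_next <- propagate_tdse(cvec, E, E, sig, sig, dt, dt / 20)
  p_a0 <- Mod(cvec[1])^2; p_a1 <- Mod(c_next[1])^2
  flux_expect <- max(0, (p_a0 - p_a1) / p_a0)
  p_hop <- hop_probabilities(c_next, sig, dt, 1)
  n_draw <- 1e4
  set.seed(123)
  hops <- sum(runif(n_draw) < sum(p_hop))
  se <- sqrt(flux_expect * (1 - flux_expect) / n_draw)
  expect_lt(abs(hops / n_draw - flux_expect), 3 * se)
})

test_that("accepted hops conserve QM energy exactly; frustrated hops change
           nothing", {
  set.seed(7)
  v <- matrix(rnorm(12, sd = 5e-4), 4, 3)
  masses <- amu_to_au(c(12, 14, 1, 16))
  qm <- c(TRUE, TRUE, TRUE, FALSE)
  energies <- c(0.0, 0.18, 0.21)
  K0 <- 0.5 * sum(masses[qm] * rowSums(v[qm, ]^2))
  # downhill: always accepted with s > 1
  hp <- attempt_hop(v, masses, qm, 3, 2, energies)
  expect_true(hp$hopped)
  expect_gt(hp$s, 1)
  K1 <- 0.5 * sum(masses[qm] * rowSums(hp$v[qm, ]^2))
  expect_lt(abs((K1 + energies[2]) - (K0 + energies[3])), 1e-12)
  # MM velocities untouched
  expect_identical(hp$v[4, ], v[4, ])
  # uphill beyond the QM kinetic energy: frustrated
  energies_far <- c(0, 0.18, 0.18 + K0 * 2)
  fr <- attempt_hop(v, masses, qm, 2, 3, energies_far)
  expect_false(fr$hopped)
  expect_identical(fr$v, v)
  expect_equal(fr$active, 2)
})

test_that("decoherence damping follows the energy-based lifetime formula", {
  cvec <- c(sqrt(0.6) + 0i, sqrt(0.4) + 0i)
  out0 <- apply_decoherence(cvec, c(0, 0.1), 1, 0.05, 0, alpha = 0.1)
  expect_equal(out0, cvec)
  # dE = 0.1, K = 0.05, alpha = 0.1 -> tau = (1/0.1)(1 + 2) = 30 a.u.
  dt <- 5
  out <- apply_decoherence(cvec, c(0, 0.1), 1, 0.05, dt, alpha = 0.1)
  expect_equal(Mod(out[2]), Mod(cvec[2]) * exp(-dt / 30), tolerance = 1e-12)
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  # huge gap: off-state amplitude killed within one step
  far <- apply_decoherence(cvec, c(0, 1e6), 1, 0.05, 1, alpha = 0.1)
  expect_lt(Mod(far[2]), 1e-10)
  # degenerate states are not damped
  deg <- apply_decoherence(cvec, c(0, 0), 1, 0.05, 10, alpha = 0.1)
  expect_equal(deg, cvec)
})

test_that("Berendsen rescaling: fixed point, monotonicity, equilibration", {
  set.seed(31)
  cl <- make_thermal_cluster(16, seed = 2)
  kb <- polhop_units$kb_hartree
  ndof <- 3 * 16
  # velocities at exactly T0: lambda = 1
  T0 <- 300
  v <- matrix(rnorm(48), 16, 3)
  K_target <- 0.5 * ndof * kb * T0
  v <- v * sqrt(K_target / (0.5 * sum(cl$masses * rowSums(v^2))))
  br <- berendsen_rescale(v, cl$masses, T0, fs_to_au(50), fs_to_au(0.5))
  expect_equal(br$lambda, 1, tolerance = 1e-12)
  expect_error(berendsen_rescale(0 * v, cl$masses, T0, 1, 1), "zero")
  # lambda monotone in T0 at fixed T_inst
  lams <- vapply(c(150, 300, 600), function(Tref)
    berendsen_rescale(v, cl$masses, Tref, fs_to_au(50), fs_to_au(0.5))$lambda,
    numeric(1))
  expect_true(all(diff(lams) > 0))

  # thermostatted run reaches and holds the target temperature
  dt <- fs_to_au(1.0)
  v <- matrix(rnorm(48), 16, 3)
  v <- v * sqrt(0.25 * K_target / (0.5 * sum(cl$masses * rowSums(v^2))))
  R <- cl$R0
  f <- cl$force_fn(R)$forces
  temps <- numeric(3000)
  for (s in seq_len(3000)) {
    st <- verlet_step(R, v, cl$masses, f, function(Rn) cl$force_fn(Rn)$forces, dt)
    R <- st$R; v <- st$v; f <- st$forces
    br <- berendsen_rescale(v, cl$masses, T0, fs_to_au(50), dt)
    v <- br$v
    temps[s] <- br$T_inst
  }
  expect_lt(abs(mean(temps[1000:3000]) - T0) / T0, 0.05)
})

test_that("harmonic wall: dead zone, restoring magnitude, energy conservation", {
  R <- rbind(c(0, 0, 5), c(0, 0, 12))
  w <- harmonic_wall(R, radius = 10, k = 0.02)
  expect_equal(w$forces[1, ], c(0, 0, 0))
  expect_equal(w$forces[2, ], c(0, 0, -2 * 0.02 * 2), tolerance = 1e-12)
  expect_equal(w$energy, 0.02 * 4, tolerance = 1e-12)

  # microcanonical run with wall: kinetic + wall potential conserved
  mass <- amu_to_au(16)
  R <- matrix(c(0, 0, 9.5), 1, 3); v <- matrix(c(0, 0, 8e-4), 1, 3)
  wf <- function(Rn) harmonic_wall(Rn, 10, 0.02)$forces
  f <- wf(R)
  e0 <- 0.5 * mass * sum(v^2) + harmonic_wall(R, 10, 0.02)$energy
  dt <- fs_to_au(0.5)
  for (s in 1:400) {
    st <- verlet_step(R, v, mass, f, wf, dt)
    R <- st$R; v <- st$v; f <- st$forces
  }
  e1 <- 0.5 * mass * sum(v^2) + harmonic_wall(R, 10, 0.02)$energy
  expect_lt(abs(e1 - e0), 1e-6)
  expect_lt(sqrt(sum(R^2)), 11)  # stayed confined
})

test_that("termination rules fire at the configured thresholds in order", {
  cfg <- sh_config()
  mk <- function(t, gap, drift) data.frame(t_fs = t, gap_ev = gap,
                                           drift_ev = drift)
  # gap below 0.2 eV -> internal conversion at that time
  tr <- mk(seq(0.5, 10, 0.5), c(rep(1, 19), 0.19), 0)
  out <- check_termination(tr, cfg)
  expect_equal(out$status, "gap_reached")
  expect_equal(out$t_ic_fs, 10)
  # drift above 0.5 eV invalidates
  tr2 <- mk(seq(0.5, 5, 0.5), 1, c(rep(0, 9), 0.6))
  out2 <- check_termination(tr2, cfg)
  expect_equal(out2$status, "drift_invalid")
  expect_false(out2$valid)
  # both in the same step: drift wins
  tr3 <- mk(1, 0.1, 0.7)
  expect_equal(check_termination(tr3, cfg)$status, "drift_invalid")
  # neither: the 100 fs cap
  tr4 <- mk(seq(0.5, 100, 0.5), 1, 0)
  expect_equal(check_termination(tr4, cfg)$status, "time_up")
  # early gap event: invalid (too short)
  tr5 <- mk(c(0.5, 1.0), c(1, 0.15), 0)
  out5 <- check_termination(tr5, cfg)
  expect_equal(out5$status, "too_short")
  expect_false(out5$valid)
  # boundary values do not fire (strict inequalities)
  tr6 <- mk(1, 0.2, 0.5)
  expect_equal(check_termination(tr6, cfg)$status, "continue")
})

test_that("surface hopping reduces to adiabatic MD without coupling", {
  fx <- make_edpt_fixture(0)
  cfg <- sh_config(seed = 5, max_time_fs = 25)
  # start on S1 of a coupling-free copy of the model: no hops can occur
  model_nc <- fx$model
  model_nc$couplings <- list()
  set.seed(9)
  v0 <- matrix(rnorm(15, sd = 1e-4), 5, 3)
  tr <- run_trajectory(model_nc, fx$R0, v0, fx$masses, 2, cfg)
  expect_equal(nrow(tr$hops), 0)
  expect_equal(unique(tr$log$active), 2)
  expect_lt(max(tr$log$drift_ev), 1e-3)
  expect_true(all(abs(tr$log$pop1 - 1) < 1e-8))
})

test_that("trajectories are bit-identical across reruns with the same seed", {
  fx <- make_edpt_fixture(0)
  cfg <- sh_config(seed = 17, max_time_fs = 15)
  set.seed(3)
  v0 <- matrix(rnorm(15, sd = 3e-4), 5, 3)
  t1 <- run_trajectory(fx$model, fx$R0, v0, fx$masses, 2, cfg,
                       trajectory_id = 4L)
  t2 <- run_trajectory(fx$model, fx$R0, v0, fx$masses, 2, cfg,
                       trajectory_id = 4L)
  expect_identical(t1$log, t2$log)
  expect_identical(t1$status, t2$status)
})

test_that("cold MM atoms never affect the electronic decisions", {
  fx <- make_edpt_fixture(0)
  cfg <- sh_config(seed = 23, max_time_fs = 15)
  set.seed(11)
  v0 <- matrix(rnorm(15, sd = 3e-4), 5, 3)
  base <- run_trajectory(fx$model, fx$R0, v0, fx$masses, 2, cfg)
  # append two distant cold MM atoms
  R_mm <- rbind(fx$R0, c(40, 0, 0), c(0, 40, 0))
  v_mm <- rbind(v0, matrix(0, 2, 3))
  with_mm <- run_trajectory(fx$model, R_mm, v_mm,
                            c(fx$masses, amu_to_au(c(16, 16))), 2, cfg,
                            qm_mask = c(rep(TRUE, 5), FALSE, FALSE))
  expect_equal(with_mm$log$active, base$log$active)
  expect_equal(with_mm$log$pop1, base$log$pop1, tolerance = 1e-12)
  expect_identical(with_mm$hops$accepted, base$hops$accepted)
  # ... and hot MM atoms do not unlock frustrated hops (QM-only energy):
  v_hot <- v_mm; v_hot[6:7, ] <- 0.05
  hot <- run_trajectory(fx$model, R_mm, v_hot,
                        c(fx$masses, amu_to_au(c(16, 16))), 2, cfg,
                        qm_mask = c(rep(TRUE, 5), FALSE, FALSE))
  expect_equal(hot$log$active, base$log$active)
  expect_identical(hot$hops$accepted, base$hops$accepted)
})

test_that("microcanonical fixture runs conserve energy at protocol settings", {
  fx <- make_edpt_fixture(0)
  set.seed(2)
  # modest thermal-scale velocities on the ground state
  v0 <- matrix(rnorm(15), 5, 3) / sqrt(fx$masses)
  K_target <- 15 * 0.5 * polhop_units$kb_hartree * 300
  v0 <- v0 * sqrt(K_target / (0.5 * sum(fx$masses * rowSums(v0^2))))
  drift_at <- function(dt_fs) {
    cfg <- sh_config(dt_fs = dt_fs, dt_electronic_fs = dt_fs / 20,
                     max_time_fs = 100, seed = 1)
    tr <- run_trajectory(fx$model, fx$R0, v0, fx$masses, 1, cfg)
    expect_equal(tr$status, "time_up")
    max(tr$log$drift_ev) / polhop_units$ev_per_hartree
  }
  d1 <- drift_at(0.5)
  expect_lt(d1, 1e-4)
  d2 <- drift_at(0.25)
  expect_gt(d1 / d2, 2.5)  # ~4x from the second-order integrator
})
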