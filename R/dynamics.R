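# Decoherence-corrected fewest-switches surface hopping: nuclear velocity
# Verlet, electronic TDSE with interpolated substeps, flux-based hopping
# probabilities, QM-only kinetic-energy conventions for hops / frustrated
# hops / decoherence, Berendsen rescaling and a harmonic confining wall for
# equilibration, and the termination rules applied to each trajectory.

#' Surface-hopping configuration
#'
#' Bundles the propagation parameters. Defaults follow the standard
#' protocol for ultrafast azine photodynamics: 0.5 fs nuclear and 0.025 fs
#' electronic time steps, a 100 fs cap, energy-based decoherence with
#' parameter 0.1 Hartree, termination when the S1/S0 gap falls below 0.2 eV,
#' invalidation at a total-energy drift above 0.5 eV, and a 5 fs minimum
#' valid length.
#'
#' @param dt_fs nuclear time step (fs).
#' @param dt_electronic_fs electronic (TDSE) substep (fs); must divide `dt_fs`.
#' @param max_time_fs maximum propagation time (fs).
#' @param decoherence_alpha Granucci-Persico decoherence parameter (Hartree).
#' @param gap_threshold_ev S1/S0 gap below which the trajectory terminates
#'   (internal conversion) (eV).
#' @param drift_threshold_ev total-energy drift (from t = 0) that invalidates
#'   a trajectory (eV).
#' @param min_valid_fs minimum length of a valid trajectory (fs).
#' @param excited_only logical: evaluate hops only among excited states
#'   (ground-state recovery is handled by the gap criterion).
#' @param seed RNG seed for the hopping draws.
#' @return an `sh_config` list.
#' @export
sh_config <- function(dt_fs = 0.5, dt_electronic_fs = 0.025,
                      max_time_fs = 100, decoherence_alpha = 0.1,
                      gap_threshold_ev = 0.2, drift_threshold_ev = 0.5,
                      min_valid_fs = 5, excited_only = TRUE, seed = 1L) {
  stopifnot(dt_fs > 0, dt_electronic_fs > 0, max_time_fs > 0,
            decoherence_alpha > 0, gap_threshold_ev > 0,
            drift_threshold_ev > 0, min_valid_fs > 0)
  n_sub <- dt_fs / dt_electronic_fs
  if (abs(n_sub - round(n_sub)) > 1e-8)
    stop("dt_electronic_fs must divide dt_fs")
  structure(list(dt_fs = dt_fs, dt_electronic_fs = dt_electronic_fs,
                 max_time_fs = max_time_fs,
                 decoherence_alpha = decoherence_alpha,
                 gap_threshold_ev = gap_threshold_ev,
                 drift_threshold_ev = drift_threshold_ev,
                 min_valid_fs = min_valid_fs, excited_only = excited_only,
                 n_sub = as.integer(round(n_sub)), seed = as.integer(seed)),
            class = "sh_config")
}

#' One velocity-Verlet step
#'
#' @param R positions (n x 3, Bohr).
#' @param v velocities (n x 3, a.u.).
#' @param masses per-atom masses (a.u.).
#' @param forces forces at `R` (n x 3, Hartree/Bohr).
#' @param force_fn function of positions returning forces at the new
#'   geometry (n x 3).
#' @param dt time step (a.u.).
#' @return list with updated `R`, `v` and the `forces` at the new geometry.
#' @export
verlet_step <- function(R, v, masses, forces, force_fn, dt) {
  v_half <- v + forces / masses * (dt / 2)
  R_new <- R + v_half * dt
  f_new <- force_fn(R_new)
  v_new <- v_half + f_new / masses * (dt / 2)
  list(R = R_new, v = v_new, forces = f_new)
}

kinetic_energy <- function(v, masses, mask = NULL) {
  if (!is.null(mask)) { v <- v[mask, , drop = FALSE]; masses <- masses[mask] }
  0.5 * sum(masses * rowSums(v * v))
}

#' Propagate the electronic TDSE across one nuclear step
#'
#' Integrates \eqn{i\dot c_I = E_I c_I - i \sum_J \sigma_{IJ} c_J} over one
#' nuclear step of length `dt`, split into substeps of length `dt_e`.
#' Energies and couplings are interpolated linearly between their values at
#' the two ends of the nuclear step, and each substep applies the exact
#' unitary exponential of the frozen (midpoint-interpolated) generator, so
#' the norm of `c` is preserved to machine precision.
#'
#' @param c complex coefficient vector (unit norm).
#' @param E0,E1 adiabatic energies at t and t + dt (Hartree).
#' @param sigma0,sigma1 antisymmetric coupling matrices at t and t + dt.
#' @param dt nuclear step (a.u.).
#' @param dt_e electronic substep (a.u.); must divide `dt`.
#' @return updated complex coefficient vector.
#' @export
propagate_tdse <- function(c, E0, E1, sigma0, sigma1, dt, dt_e) {
  if (any(!is.finite(c(E0, E1, sigma0, sigma1))))
    stop("non-finite electronic inputs")
  n_sub <- round(dt / dt_e)
  if (abs(dt / dt_e - n_sub) > 1e-8) stop("dt_e must divide dt")
  for (m in seq_len(n_sub)) {
    th <- (m - 0.5) / n_sub
    E <- (1 - th) * E0 + th * E1
    s <- (1 - th) * sigma0 + th * sigma1
    H <- diag(E + 0i) - 1i * s      # Hermitian for antisymmetric real sigma
    eig <- eigen(H, symmetric = TRUE)
    ph <- exp(-1i * eig$values * dt_e)
    c <- eig$vectors %*% (ph * (Conj(t(eig$vectors)) %*% c))
  }
  as.complex(c)
}

#' Fewest-switches hopping probabilities
#'
#' Tully flux formula: the probability of hopping from the active state to
#' state J over a step is the population flow out of the active state into J,
#' \eqn{P_J = \max(0,\; 2\Delta t\,\sigma_{aJ}\,{\rm Re}(c_J c_a^*)/|c_a|^2)},
#' clamped so the total is at most 1.
#'
#' @param c complex coefficients.
#' @param sigma antisymmetric coupling matrix (a.u.^-1).
#' @param dt nuclear step (a.u.).
#' @param active active state index.
#' @return numeric vector of per-state probabilities (zero for the active
#'   state).
#' @export
hop_probabilities <- function(c, sigma, dt, active) {
  n <- length(c)
  p <- numeric(n)
  pa <- Re(c[active] * Conj(c[active]))
  if (pa < 1e-12) {
    warning("active-state population below 1e-12; no hops proposed")
    return(p)
  }
  for (J in seq_len(n)) {
    if (J == active) next
    p[J] <- max(0, 2 * dt * sigma[active, J] * Re(c[J] * Conj(c[active])) / pa)
  }
  tot <- sum(p)
  if (tot > 1) p <- p / tot
  p
}

#' Attempt a hop with QM-only kinetic-energy accounting
#'
#' The hop is accepted when the kinetic energy of the QM atoms can pay the
#' potential-energy difference; accepted hops rescale the QM-atom velocities
#' by a single scalar so that QM kinetic plus potential energy is conserved
#' exactly. Otherwise the hop is frustrated and nothing changes (velocities
#' keep their original direction).
#'
#' @param v velocities (n x 3, a.u.).
#' @param masses masses (a.u.).
#' @param qm_mask logical per-atom QM mask.
#' @param active current active state.
#' @param target proposed state (different from `active`).
#' @param energies adiabatic energies (Hartree).
#' @return list with `hopped` (logical), updated `v`, new `active`, and the
#'   rescale factor `s` (NA when frustrated).
#' @export
attempt_hop <- function(v, masses, qm_mask, active, target, energies) {
  stopifnot(target != active)
  K <- kinetic_energy(v, masses, qm_mask)
  dE <- energies[active] - energies[target]
  if (K + dE < 0 || K <= 0)
    return(list(hopped = FALSE, v = v, active = active, s = NA_real_))
  s <- sqrt(1 + dE / K)
  v[qm_mask, ] <- v[qm_mask, , drop = FALSE] * s
  list(hopped = TRUE, v = v, active = target, s = s)
}

#' Energy-based decoherence correction
#'
#' Granucci-Persico damping: every non-active amplitude decays with lifetime
#' \eqn{\tau_J = \frac{1}{|E_J - E_a|}\left(1 + \frac{\alpha}{K_{qm}}\right)}
#' over the step, and the active amplitude is rescaled to restore unit norm.
#' States degenerate with the active one are not damped.
#'
#' @param c complex coefficients (unit norm).
#' @param energies adiabatic energies (Hartree).
#' @param active active state index.
#' @param K_qm kinetic energy of the QM atoms (Hartree), > 0.
#' @param dt step length (a.u.).
#' @param alpha decoherence parameter (Hartree), default 0.1.
#' @return updated complex coefficients (unit norm).
#' @export
apply_decoherence <- function(c, energies, active, K_qm, dt, alpha = 0.1) {
  stopifnot(K_qm > 0)
  n <- length(c)
  for (J in seq_len(n)) {
    if (J == active) next
    dE <- abs(energies[J] - energies[active])
    if (dE < 1e-12) next
    tau <- (1 / dE) * (1 + alpha / K_qm)
    c[J] <- c[J] * exp(-dt / tau)
  }
  rest <- sum(Mod(c[-active])^2)
  pa <- Mod(c[active])^2
  if (pa > 0) c[active] <- c[active] * sqrt(max(0, 1 - rest) / pa)
  c
}

#' Berendsen velocity rescaling
#'
#' Weak-coupling thermostat for equilibration runs (never during surface
#' hopping): velocities are scaled by
#' \eqn{\lambda = \sqrt{1 + (\Delta t/\tau)(T_0/T - 1)}}.
#'
#' @param v velocities (n x 3, a.u.).
#' @param masses masses (a.u.).
#' @param T0 reference temperature (K).
#' @param tau coupling time constant (a.u. time).
#' @param dt step (a.u.).
#' @param ndof number of degrees of freedom for the instantaneous
#'   temperature; defaults to 3n.
#' @return list with rescaled `v`, the factor `lambda` and `T_inst` (K).
#' @export
berendsen_rescale <- function(v, masses, T0, tau, dt, ndof = NULL) {
  if (is.null(ndof)) ndof <- 3 * length(masses)
  K <- kinetic_energy(v, masses)
  T_inst <- 2 * K / (ndof * polhop_units$kb_hartree)
  if (T_inst <= 0) stop("instantaneous temperature is zero")
  lambda <- sqrt(1 + (dt / tau) * (T0 / T_inst - 1))
  list(v = v * lambda, lambda = lambda, T_inst = T_inst)
}

#' Harmonic confining wall
#'
#' Radial restoring force \eqn{-2k\,(r - r_{wall})\hat r} on every atom
#' outside the wall radius; zero inside.
#'
#' @param R positions (n x 3, Bohr).
#' @param radius wall radius (Bohr).
#' @param k force constant (Hartree/Bohr^2).
#' @param center wall center (length-3, Bohr), default origin.
#' @return list with `forces` (n x 3) and potential `energy` (Hartree).
#' @export
harmonic_wall <- function(R, radius, k, center = c(0, 0, 0)) {
  stopifnot(radius > 0)
  dr <- sweep(matrix(R, ncol = 3), 2, center)
  d <- sqrt(rowSums(dr * dr))
  out <- pmax(0, d - radius)
  F <- matrix(0, nrow(dr), 3)
  idx <- which(out > 0)
  for (i in idx) F[i, ] <- -2 * k * out[i] * dr[i, ] / d[i]
  list(forces = F, energy = k * sum(out^2))
}

#' Termination rules for a trajectory trace
#'
#' Scans a per-step trace (time, S1/S0 gap, cumulative total-energy drift)
#' and applies the termination rules in precedence order within each step:
#' drift invalidation first, then gap-based internal conversion, then the
#' time cap. Gap terminations earlier than the minimum valid length are
#' flagged invalid (`too_short`).
#'
#' @param trace data.frame with columns `t_fs`, `gap_ev`, `drift_ev` (one
#'   row per step, in time order).
#' @param config an `sh_config`.
#' @return list with `status` (`"continue"`, `"gap_reached"`,
#'   `"drift_invalid"`, `"time_up"`), event time `t_fs` (NA while
#'   continuing), `t_ic_fs` (internal-conversion time, NA unless the gap rule
#'   fired on a valid trajectory) and logical `valid`.
#' @export
check_termination <- function(trace, config) {
  for (i in seq_len(nrow(trace))) {
    if (trace$drift_ev[i] > config$drift_threshold_ev)
      return(list(status = "drift_invalid", t_fs = trace$t_fs[i],
                  t_ic_fs = NA_real_, valid = FALSE))
    if (trace$gap_ev[i] < config$gap_threshold_ev) {
      ok <- trace$t_fs[i] > config$min_valid_fs
      return(list(status = if (ok) "gap_reached" else "too_short",
                  t_fs = trace$t_fs[i],
                  t_ic_fs = if (ok) trace$t_fs[i] else NA_real_,
                  valid = ok))
    }
    if (trace$t_fs[i] >= config$max_time_fs)
      return(list(status = "time_up", t_fs = trace$t_fs[i],
                  t_ic_fs = NA_real_, valid = TRUE))
  }
  list(status = "continue", t_fs = NA_real_, t_ic_fs = NA_real_, valid = TRUE)
}

#' Run one surface-hopping trajectory
#'
#' Full DC-FSSH loop on a diabatic model (optionally embedded in a
#' multipolar polarizable environment): electronic evaluation with phase
#' tracking, velocity Verlet on the active surface, overlap-based HST
#' couplings, TDSE substep integration with linear interpolation, one
#' hopping draw per nuclear step (among excited states by default),
#' energy-based decoherence, and the termination rules. Environment sites
#' are held fixed; optional extra non-QM atoms (rows of `R` where `qm_mask`
#' is FALSE) feel no model forces and never enter the electronic decisions.
#'
#' @param model a `diabatic_model`.
#' @param R initial positions (n x 3, Bohr); rows with `qm_mask` TRUE must
#'   match the model's atoms in order.
#' @param v initial velocities (n x 3, a.u.).
#' @param masses masses (a.u.).
#' @param initial_state initial active state (adiabatic index, 1 = ground).
#' @param config an `sh_config`.
#' @param env optional `multipole_set`.
#' @param qm_mask logical per-atom mask; default all TRUE.
#' @param include_lr include LR environment shifts (and their
#'   finite-difference gradient for the active state) when `env` is
#'   polarizable.
#' @param trajectory_id integer id recorded in the output and combined with
#'   the config seed for this trajectory's RNG stream.
#' @return a `trajectory` object: list with `log` (per-step data.frame:
#'   time, adiabatic energies in eV, active state, populations, monitored
#'   distances in Angstrom), `frames` (list of geometries), `status`,
#'   `t_ic_fs`, `valid`, `seed`, `config`, `hops` (data.frame of accepted /
#'   frustrated hop events).
#' @export
run_trajectory <- function(model, R, v, masses, initial_state, config,
                           env = NULL, qm_mask = NULL, include_lr = TRUE,
                           trajectory_id = 0L) {
  R <- matrix(R, ncol = 3); v <- matrix(v, ncol = 3)
  n_at <- nrow(R)
  if (is.null(qm_mask)) qm_mask <- rep(TRUE, n_at)
  stopifnot(sum(qm_mask) == model$n_atoms, length(masses) == n_at,
            all(masses > 0))
  n <- model$n_states
  dt <- fs_to_au(config$dt_fs)
  dt_e <- fs_to_au(config$dt_electronic_fs)
  n_steps <- ceiling(config$max_time_fs / config$dt_fs)
  polarizable <- !is.null(env) && any(env$alphas > 0) && include_lr

  # private RNG stream for this trajectory
  rng <- local({
    seed <- (config$seed * 1000003L + as.integer(trajectory_id)) %% 2147483647L
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    st <- get(".Random.seed", .GlobalEnv)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    list(seed = seed, state = st)
  })
  rng_state <- rng$state
  draw_uniform <- function() {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    assign(".Random.seed", rng_state, .GlobalEnv)
    u <- stats::runif(1)
    rng_state <<- get(".Random.seed", .GlobalEnv)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    u
  }

  active <- initial_state
  evaluate_at <- function(Rfull, prev_U) {
    evaluate_states(model, Rfull[qm_mask, , drop = FALSE], env = env,
                    prev_U = prev_U, include_lr = include_lr,
                    lr_gradient_states = if (polarizable) active else integer(0))
  }
  forces_from <- function(res) {
    F <- matrix(0, n_at, 3)
    F[qm_mask, ] <- -res$gradients[active, , ]
    F
  }

  res <- evaluate_at(R, NULL)
  forces <- forces_from(res)
  cvec <- complex(n); cvec[active] <- 1 + 0i
  sigma_prev <- matrix(0, n, n)
  E0_tot <- kinetic_energy(v, masses) + res$energies[active]

  log_rows <- vector("list", n_steps)
  frames <- vector("list", n_steps + 1)
  frames[[1]] <- R
  hops <- list()
  trace <- data.frame(t_fs = numeric(0), gap_ev = numeric(0),
                      drift_ev = numeric(0))
  status <- "time_up"; t_end <- config$max_time_fs

  for (step in seq_len(n_steps)) {
    res_old <- res
    vv <- verlet_step(R, v, masses, forces, function(Rn) {
      res <<- evaluate_at(Rn, res_old$U)
      forces_from(res)
    }, dt)
    R <- vv$R; v <- vv$v; forces <- vv$forces
    t_fs <- step * config$dt_fs
    frames[[step + 1]] <- R

    ov <- model_state_overlap(res_old$U, res$U, dt)
    sigma <- hst_coupling(ov)
    cvec <- propagate_tdse(cvec, res_old$energies, res$energies,
                           sigma_prev, sigma, dt, dt_e)

    # one uniform draw per nuclear step decides the hop
    p <- hop_probabilities(cvec, sigma, dt, active)
    if (config$excited_only) p[1] <- 0
    xi <- draw_uniform()
    cum <- cumsum(p)
    target <- if (any(xi < cum)) which(xi < cum)[1] else 0L
    if (target > 0 && target != active) {
      hp <- attempt_hop(v, masses, qm_mask, active, target, res$energies)
      hops[[length(hops) + 1]] <- data.frame(
        t_fs = t_fs, from = active, to = target, accepted = hp$hopped)
      if (hp$hopped) {
        v <- hp$v; active <- hp$active
        forces <- forces_from(res)
      }
    }
    K_qm <- kinetic_energy(v, masses, qm_mask)
    if (K_qm > 0)
      cvec <- apply_decoherence(cvec, res$energies, active, K_qm, dt,
                                config$decoherence_alpha)
    sigma_prev <- sigma

    E_tot <- kinetic_energy(v, masses) + res$energies[active]
    gap_ev <- hartree_to_ev(res$energies[2] - res$energies[1])
    drift_ev <- hartree_to_ev(abs(E_tot - E0_tot))
    Rqm <- R[qm_mask, , drop = FALSE]
    log_rows[[step]] <- data.frame(
      t_fs = t_fs, active = active,
      e_active_ev = hartree_to_ev(res$energies[active]),
      gap_ev = gap_ev, drift_ev = drift_ev,
      t(stats::setNames(hartree_to_ev(res$energies), paste0("E", seq_len(n) - 1, "_ev"))),
      t(stats::setNames(Mod(cvec)^2, paste0("pop", seq_len(n) - 1))))
    trace <- rbind(trace, data.frame(t_fs = t_fs, gap_ev = gap_ev,
                                     drift_ev = drift_ev))
    term <- check_termination(trace[nrow(trace), , drop = FALSE], config)
    if (term$status != "continue") {
      status <- term$status; t_end <- t_fs
      if (term$status %in% c("gap_reached", "too_short") &&
          t_fs <= config$min_valid_fs) status <- "too_short"
      break
    }
  }
  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  frames <- frames[!vapply(frames, is.null, logical(1))]
  valid <- !(status %in% c("drift_invalid", "too_short"))
  t_ic <- if (status == "gap_reached") t_end else NA_real_
  structure(list(log = log, frames = frames, status = status,
                 t_end_fs = t_end, t_ic_fs = t_ic, valid = valid,
                 seed = rng$seed, trajectory_id = trajectory_id,
                 active_final = active, config = config,
                 qm_mask = qm_mask, atoms = model$atoms,
                 hops = if (length(hops)) do.call(rbind, hops) else
                   data.frame(t_fs = numeric(0), from = integer(0),
                              to = integer(0), accepted = logical(0))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory", x$trajectory_id, ": ", x$status, " at ",
      x$t_end_fs, " fs; ", sum(x$hops$accepted), " hops (",
      sum(!x$hops$accepted), " frustrated)\n", sep = "")
  invisible(x)
}
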