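# Initial-condition machinery: numerical Hessians from analytic gradients,
# normal-mode analysis with translation/rotation projection, harmonic
# ground-state Wigner sampling, and oscillator-strength-weighted selection
# of initial excited states inside an energy window.

#' Numerical Hessian from analytic gradients
#'
#' Central finite differences of a gradient function, symmetrized as
#' \eqn{(H + H^T)/2}. Exact (to round-off) for quadratic potentials.
#'
#' @param gradient_fn function taking an `n x 3` geometry (Bohr) and
#'   returning an `n x 3` gradient (Hartree/Bohr).
#' @param R0 reference geometry (`n x 3`, Bohr), expected near a stationary
#'   point (a warning is emitted otherwise).
#' @param step displacement (Bohr), default 0.01.
#' @return `3n x 3n` symmetric Hessian (Hartree/Bohr^2), coordinates ordered
#'   atom-major (x1, y1, z1, x2, ...).
#' @export
numerical_hessian <- function(gradient_fn, R0, step = 0.01) {
  R0 <- matrix(R0, ncol = 3)
  n <- nrow(R0)
  g0 <- gradient_fn(R0)
  if (sqrt(sum(g0^2)) > 1e-3)
    warning("gradient norm at R0 is ", format(sqrt(sum(g0^2))),
            "; R0 does not look like a stationary point")
  H <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) for (x in 1:3) {
    col <- 3 * (a - 1) + x
    Rp <- R0; Rp[a, x] <- Rp[a, x] + step
    Rm <- R0; Rm[a, x] <- Rm[a, x] - step
    gp <- tryCatch(gradient_fn(Rp), error = function(e)
      stop("gradient evaluation failed at +", step, " Bohr displacement of atom ",
           a, " coordinate ", x, ": ", conditionMessage(e)))
    gm <- tryCatch(gradient_fn(Rm), error = function(e)
      stop("gradient evaluation failed at -", step, " Bohr displacement of atom ",
           a, " coordinate ", x, ": ", conditionMessage(e)))
    H[, col] <- as.numeric(t(gp - gm)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Normal-mode analysis of a Hessian
#'
#' Mass-weights the Hessian, projects out rigid translations and rotations
#' (generators built at `R0`, orthonormalized; degenerate generators of
#' linear systems are dropped automatically), and diagonalizes. Imaginary
#' frequencies (negative eigenvalues of the projected mass-weighted Hessian)
#' are reported, not dropped.
#'
#' @param H `3n x 3n` Cartesian Hessian (Hartree/Bohr^2), atom-major order.
#' @param masses per-atom masses (a.u.).
#' @param R0 reference geometry (`n x 3`, Bohr).
#' @param zero_tol eigenvalue magnitude below which a mode counts as a
#'   projected-out zero mode.
#' @return a `normal_modes` object: `omega` (a.u., ascending over real
#'   modes), `imaginary` (logical per mode), `modes` (mass-weighted
#'   orthonormal columns), `masses`, `R0`, `n_zero` (count of projected
#'   rigid-body modes).
#' @export
normal_mode_analysis <- function(H, masses, R0, zero_tol = 1e-10) {
  R0 <- matrix(R0, ncol = 3)
  n <- nrow(R0)
  stopifnot(nrow(H) == 3 * n, max(abs(H - t(H))) < 1e-8)
  sm <- rep(sqrt(masses), each = 3)
  Hmw <- H / outer(sm, sm)
  # rigid-body generators in mass-weighted coordinates
  com <- colSums(R0 * masses) / sum(masses)
  Rc <- sweep(R0, 2, com)
  gens <- list()
  for (x in 1:3) {
    v <- matrix(0, n, 3); v[, x] <- 1
    gens[[length(gens) + 1]] <- as.numeric(t(v * sqrt(masses)))
  }
  axes <- diag(3)
  for (x in 1:3) {
    v <- t(vapply(seq_len(n), function(i)
      crossprod_3(axes[x, ], Rc[i, ]), numeric(3)))
    gens[[length(gens) + 1]] <- as.numeric(t(v * sqrt(masses)))
  }
  B <- do.call(cbind, gens)
  qr_B <- qr(B)
  rank <- sum(abs(diag(qr.R(qr_B))) > 1e-8)
  Q <- qr.Q(qr_B)[, seq_len(rank), drop = FALSE]
  P <- diag(3 * n) - tcrossprod(Q)
  Hp <- P %*% Hmw %*% P
  Hp <- (Hp + t(Hp)) / 2
  eig <- eigen(Hp, symmetric = TRUE)
  lam <- rev(eig$values)
  V <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  zero <- abs(lam) < zero_tol
  keep <- !zero
  lam <- lam[keep]; V <- V[, keep, drop = FALSE]
  ord <- order(lam)
  lam <- lam[ord]; V <- V[, ord, drop = FALSE]
  structure(list(omega = sqrt(abs(lam)), imaginary = lam < 0,
                 modes = V, masses = masses, R0 = R0,
                 n_zero = sum(zero)),
            class = "normal_modes")
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.normal_modes <- function(x, ...) {
  wn <- x$omega * 219474.63  # a.u. -> cm^-1
  cat("normal_modes:", length(x$omega), "modes (", x$n_zero,
      "rigid-body projected,", sum(x$imaginary), "imaginary )\n")
  cat("  frequencies (cm^-1):", paste(sprintf("%.0f", wn), collapse = " "), "\n")
  invisible(x)
}

#' Harmonic ground-state Wigner sampling
#'
#' Draws positions and momenta per normal mode from the Wigner density of
#' the vibrational ground state, \eqn{Q \sim N(0, 1/(2\omega))},
#' \eqn{P \sim N(0, \omega/2)} (variances, mass-weighted a.u.), and
#' transforms to Cartesian geometries and velocities.
#'
#' @param modes a `normal_modes` object.
#' @param n number of samples.
#' @param seed RNG seed (deterministic output).
#' @param include indices of modes to sample; default all. Imaginary
#'   frequencies in the sampled set are an error and must be excluded
#'   explicitly.
#' @param sample_velocities logical; `FALSE` gives zero initial velocities.
#' @return list with `geometries` (`n` x atoms x 3 array, Bohr),
#'   `velocities` (same shape, a.u.), and the per-mode `Q`, `P` draws
#'   (`n x n_modes`).
#' @export
wigner_sample <- function(modes, n, seed = 1, include = NULL,
                          sample_velocities = TRUE) {
  if (is.null(include)) include <- seq_along(modes$omega)
  if (any(modes$imaginary[include]))
    stop("imaginary frequencies in the sampled mode set; exclude them explicitly")
  w <- modes$omega[include]
  if (any(w < 1e-8)) stop("near-zero frequency in the sampled mode set")
  set.seed(seed %% 2147483647L)
  nm <- length(include)
  Q <- matrix(stats::rnorm(n * nm), n, nm) %*% diag(sqrt(1 / (2 * w)), nm)
  P <- matrix(stats::rnorm(n * nm), n, nm) %*% diag(sqrt(w / 2), nm)
  L <- modes$modes[, include, drop = FALSE]
  sm <- rep(sqrt(modes$masses), each = 3)
  nat <- nrow(modes$R0)
  geoms <- array(0, c(n, nat, 3))
  vels <- array(0, c(n, nat, 3))
  for (s in seq_len(n)) {
    dx <- as.numeric(L %*% Q[s, ]) / sm
    geoms[s, , ] <- modes$R0 + matrix(dx, nat, 3, byrow = TRUE)
    if (sample_velocities) {
      dv <- as.numeric(L %*% P[s, ]) / sm
      vels[s, , ] <- matrix(dv, nat, 3, byrow = TRUE)
    }
  }
  list(geometries = geoms, velocities = vels, Q = Q, P = P,
       include = include)
}

#' Stochastic selection of initial conditions
#'
#' Builds the candidate pool of (sample, excited state) pairs whose vertical
#' excitation energy lies within the window around the reference energy,
#' then draws initial conditions with acceptance probability proportional
#' to the state's oscillator strength (f / f_max).
#'
#' @param samples a `wigner_sample()` result (or any list with a
#'   `geometries` array and `velocities` array).
#' @param electronic_fn function of a geometry returning a list/object with
#'   `energies` and `f` (e.g. a closure over [evaluate_states()]).
#' @param ref_energy reference excitation energy (Hartree).
#' @param window full energy width (Hartree): candidates satisfy
#'   \eqn{|\Delta E_I - E_{ref}| \le} `window`/2.
#' @param target_state_pool adiabatic state indices eligible as initial
#'   states (> 1).
#' @param n number of initial conditions to draw.
#' @param seed RNG seed.
#' @param replace draw with replacement (default); without replacement the
#'   pool must contain at least `n` accepted candidates.
#' @return list with `conditions` (list of `geometry`, `velocities`,
#'   `state`, `sample`, `excitation_ev`, `f`) and the full candidate `pool`
#'   data.frame.
#' @export
select_initial_conditions <- function(samples, electronic_fn, ref_energy,
                                      window, target_state_pool, n,
                                      seed = 1, replace = TRUE) {
  stopifnot(window > 0)
  ns <- dim(samples$geometries)[1]
  pool <- list()
  e_seen <- c()
  for (s in seq_len(ns)) {
    res <- electronic_fn(samples$geometries[s, , ])
    for (I in target_state_pool) {
      dE <- res$energies[I] - res$energies[1]
      e_seen <- c(e_seen, dE)
      if (abs(dE - ref_energy) <= window / 2)
        pool[[length(pool) + 1]] <- data.frame(
          sample = s, state = I, excitation = dE, f = res$f[I])
    }
  }
  if (length(pool) == 0)
    stop("empty candidate pool: window ", format(hartree_to_ev(window)),
         " eV around ", format(hartree_to_ev(ref_energy)),
         " eV; excitations seen span [",
         format(hartree_to_ev(min(e_seen))), ", ",
         format(hartree_to_ev(max(e_seen))), "] eV")
  pool <- do.call(rbind, pool)
  fmax <- max(pool$f)
  if (fmax <= 0)
    stop("all candidate oscillator strengths are zero; nothing selectable")
  set.seed(seed %% 2147483647L)
  chosen <- integer(0)
  available <- seq_len(nrow(pool))
  guard <- 0L
  while (length(chosen) < n) {
    guard <- guard + 1L
    if (guard > 1e6) stop("initial-condition selection did not terminate")
    idx <- if (replace) sample(nrow(pool), 1)
           else { if (length(available) == 0) stop("pool exhausted (replace = FALSE)");
                  available[sample.int(length(available), 1)] }
    if (stats::runif(1) <= pool$f[idx] / fmax) {
      chosen <- c(chosen, idx)
      if (!replace) available <- setdiff(available, idx)
    }
  }
  conditions <- lapply(chosen, function(idx) {
    s <- pool$sample[idx]
    list(geometry = samples$geometries[s, , ],
         velocities = samples$velocities[s, , ],
         state = pool$state[idx], sample = s,
         excitation_ev = hartree_to_ev(pool$excitation[idx]),
         f = pool$f[idx])
  })
  list(conditions = conditions, pool = pool)
}
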