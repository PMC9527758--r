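# Analytic multi-state diabatic electronic models. Diagonal diabats are sums
# of pairwise Morse / harmonic / exponential-repulsion terms; couplings are
# constants plus Gaussians of an interatomic distance. Diagonalization gives
# adiabatic energies; gradients follow from the Hellmann-Feynman rule
# g_I = (U' dH/dR U)_II, exact for eigenvectors of an analytic H(R).

#' Construct an analytic diabatic model
#'
#' @param n_states number of diabatic (= adiabatic) states.
#' @param n_atoms number of atoms the model potentials act on.
#' @param terms list (length `n_states`) of per-state term lists. Each term is
#'   a list with a `type` field: `"harm"` (`i`, `j`, `k`, `r0`),
#'   `"morse"` (`i`, `j`, `D`, `a`, `r0`), `"rep"` (`i`, `j`, `A`, `b`),
#'   or `"const"` (`value`). Distances in Bohr, energies in Hartree.
#' @param couplings list of couplings, each a list with `i`, `j` (state
#'   indices), optional `const`, and optional Gaussian part `gauss =
#'   list(i, j, A, r0, w)` evaluated on the distance between atoms `i`, `j`:
#'   \eqn{A \exp(-(r-r_0)^2/(2w^2))}.
#' @param state_charges `n_states x n_atoms` matrix of diabatic per-state
#'   atomic charges (a.u.).
#' @param trans_charges `n_states x n_atoms` matrix of per-diabat transition
#'   weights; each row must sum to zero (model source of transition
#'   densities).
#' @param trans_dipoles `n_states x n_states x 3` array of diabatic
#'   transition dipoles (a.u.); symmetric with zero diagonal.
#' @param ct_labels logical vector marking charge-transfer diabats.
#' @param atoms optional character atom labels.
#' @return an object of class `diabatic_model`.
#' @export
diabatic_model <- function(n_states, n_atoms, terms, couplings = list(),
                           state_charges = NULL, trans_charges = NULL,
                           trans_dipoles = NULL, ct_labels = NULL,
                           atoms = NULL) {
  stopifnot(length(terms) == n_states)
  if (is.null(state_charges)) state_charges <- matrix(0, n_states, n_atoms)
  if (is.null(trans_charges)) trans_charges <- matrix(0, n_states, n_atoms)
  if (any(abs(rowSums(trans_charges)) > 1e-10))
    stop("per-diabat transition weights must sum to zero")
  if (is.null(trans_dipoles)) trans_dipoles <- array(0, c(n_states, n_states, 3))
  if (is.null(ct_labels)) ct_labels <- rep(FALSE, n_states)
  stopifnot(length(ct_labels) == n_states,
            nrow(state_charges) == n_states, ncol(state_charges) == n_atoms)
  for (cp in couplings)
    stopifnot(cp$i >= 1, cp$j >= 1, cp$i <= n_states, cp$j <= n_states,
              cp$i != cp$j)
  if (is.null(atoms)) atoms <- paste0("X", seq_len(n_atoms))
  structure(list(n_states = n_states, n_atoms = n_atoms, terms = terms,
                 couplings = couplings, state_charges = state_charges,
                 trans_charges = trans_charges, trans_dipoles = trans_dipoles,
                 ct_labels = ct_labels, atoms = atoms),
            class = "diabatic_model")
}

#' @export
print.diabatic_model <- function(x, ...) {
  cat("diabatic_model:", x$n_states, "states,", x$n_atoms, "atoms,",
      sum(x$ct_labels), "CT-labeled\n")
  invisible(x)
}

# value and d(value)/dr of a pairwise term at distance r
term_value <- function(tm, r) {
  switch(tm$type,
    harm  = 0.5 * tm$k * (r - tm$r0)^2,
    morse = tm$D * (1 - exp(-tm$a * (r - tm$r0)))^2,
    rep   = tm$A * exp(-tm$b * r),
    stop("unknown term type ", tm$type))
}
term_deriv <- function(tm, r) {
  switch(tm$type,
    harm  = tm$k * (r - tm$r0),
    morse = { e <- exp(-tm$a * (r - tm$r0)); 2 * tm$D * tm$a * (1 - e) * e },
    rep   = -tm$A * tm$b * exp(-tm$b * r),
    stop("unknown term type ", tm$type))
}

coupling_value <- function(cp, R) {
  v <- if (is.null(cp$const)) 0 else cp$const
  if (!is.null(cp$gauss)) {
    g <- cp$gauss
    r <- sqrt(sum((R[g$i, ] - R[g$j, ])^2))
    v <- v + g$A * exp(-(r - g$r0)^2 / (2 * g$w^2))
  }
  v
}

# add dV/dR of a pairwise interaction (chain rule on the distance) to G
add_pair_gradient <- function(G, R, i, j, dvdr) {
  dr <- R[i, ] - R[j, ]
  d <- sqrt(sum(dr * dr))
  u <- dr / d
  G[i, ] <- G[i, ] + dvdr * u
  G[j, ] <- G[j, ] - dvdr * u
  G
}

# diabatic H(R) without environment
diabatic_hamiltonian <- function(model, R) {
  n <- model$n_states
  H <- matrix(0, n, n)
  for (k in seq_len(n)) {
    v <- 0
    for (tm in model$terms[[k]]) {
      if (tm$type == "const") { v <- v + tm$value; next }
      r <- sqrt(sum((R[tm$i, ] - R[tm$j, ])^2))
      v <- v + term_value(tm, r)
    }
    H[k, k] <- v
  }
  for (cp in model$couplings) {
    v <- coupling_value(cp, R)
    H[cp$i, cp$j] <- H[cp$i, cp$j] + v
    H[cp$j, cp$i] <- H[cp$j, cp$i] + v
  }
  H
}

# sign-fix eigenvector columns: align with prev_U when given, else make the
# first element of significant magnitude positive
fix_phases <- function(U, prev_U = NULL) {
  for (j in seq_len(ncol(U))) {
    s <- if (!is.null(prev_U)) sign(sum(prev_U[, j] * U[, j]))
         else sign(U[which(abs(U[, j]) > 1e-8)[1], j])
    if (!is.na(s) && s < 0) U[, j] <- -U[, j]
  }
  U
}

#' Evaluate a diabatic model at a geometry
#'
#' Diagonalizes the diabatic Hamiltonian (plus, when an environment is
#' given, the electrostatic interaction of each diabat's atomic charges with
#' the environment's static multipoles on the diagonal) and returns
#' adiabatic energies, eigenvectors, Hellmann-Feynman gradients, oscillator
#' strengths, state/transition charges and, for a polarizable environment,
#' the linear-response shift of each excited state added to its energy.
#'
#' @param model a `diabatic_model`.
#' @param R `n_atoms x 3` geometry (Bohr).
#' @param env optional `multipole_set` environment.
#' @param prev_U previous-step eigenvector matrix for phase tracking (and
#'   deterministic ordering at degeneracies); `NULL` to use the
#'   first-nonzero-positive sign convention.
#' @param include_lr logical; add the LR environment shift of each excited
#'   state (requires polarizable sites in `env`).
#' @param lr_gradient_states integer states whose gradient should include a
#'   central-finite-difference derivative of the LR shift (used for the
#'   active state during dynamics in a polarizable environment).
#' @param lr_step displacement (Bohr) for the LR-shift gradient.
#' @param tol PCG tolerance for induced-dipole solves.
#' @return an `electronic_result`: `energies` (ascending, Hartree), `U`,
#'   `gradients` (`n_states x n_atoms x 3`, Hartree/Bohr), `f` (oscillator
#'   strengths from the ground state), `state_charges`, `trans_charges`
#'   (`n_states x n_states x n_atoms`), `lr_shifts`, `H`.
#' @export
evaluate_states <- function(model, R, env = NULL, prev_U = NULL,
                            include_lr = TRUE, lr_gradient_states = integer(0),
                            lr_step = 1e-3, tol = 1e-8) {
  R <- matrix(R, ncol = 3)
  stopifnot(nrow(R) == model$n_atoms)
  n <- model$n_states
  H <- diabatic_hamiltonian(model, R)
  V_env <- NULL
  if (!is.null(env)) {
    V_env <- multipole_potential(env, R)
    for (k in seq_len(n))
      H[k, k] <- H[k, k] + sum(model$state_charges[k, ] * V_env)
  }
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  E <- eig$values[ord]
  U <- eig$vectors[, ord, drop = FALSE]
  # deterministic tie-break at (near-)degeneracies: maximum overlap with the
  # previous step when history exists, else diabatic index order
  dgn <- which(diff(E) < 1e-12)
  for (d in dgn) {
    pair <- c(d, d + 1)
    ref <- if (!is.null(prev_U)) prev_U[, pair, drop = FALSE] else diag(n)[, pair, drop = FALSE]
    ov <- abs(crossprod(ref, U[, pair, drop = FALSE]))
    if (ov[1, 2] + ov[2, 1] > ov[1, 1] + ov[2, 2])
      U[, pair] <- U[, pair[c(2, 1)]]
  }
  U <- fix_phases(U, prev_U)

  # Hellmann-Feynman gradients
  G <- array(0, c(n, model$n_atoms, 3))
  E_env <- if (!is.null(env)) multipole_field_at(env, R) else NULL
  for (k in seq_len(n)) {
    Gk <- matrix(0, model$n_atoms, 3)
    for (tm in model$terms[[k]]) {
      if (tm$type == "const") next
      r <- sqrt(sum((R[tm$i, ] - R[tm$j, ])^2))
      Gk <- add_pair_gradient(Gk, R, tm$i, tm$j, term_deriv(tm, r))
    }
    if (!is.null(env))
      Gk <- Gk - model$state_charges[k, ] * E_env
    w <- U[k, ]^2  # weight of diabat k in each adiabatic state
    for (I in seq_len(n)) G[I, , ] <- G[I, , ] + w[I] * Gk
  }
  for (cp in model$couplings) {
    if (is.null(cp$gauss)) next
    g <- cp$gauss
    r <- sqrt(sum((R[g$i, ] - R[g$j, ])^2))
    dvdr <- -g$A * (r - g$r0) / g$w^2 * exp(-(r - g$r0)^2 / (2 * g$w^2))
    Gc <- add_pair_gradient(matrix(0, model$n_atoms, 3), R, g$i, g$j, dvdr)
    for (I in seq_len(n))
      G[I, , ] <- G[I, , ] + 2 * U[cp$i, I] * U[cp$j, I] * Gc
  }

  # adiabatic state charges and transition charges
  sq <- t(U^2) %*% model$state_charges            # n_states x n_atoms
  tq <- array(0, c(n, n, model$n_atoms))
  for (I in seq_len(n)) for (J in seq_len(n)) {
    if (I == J) next
    tq[I, J, ] <- colSums(U[, I] * U[, J] * model$trans_charges)
  }

  # adiabatic transition dipoles and oscillator strengths from the ground state
  f <- numeric(n)
  for (I in 2:n) {
    mu <- vapply(1:3, function(a)
      sum(outer(U[, 1], U[, I]) * model$trans_dipoles[, , a]), numeric(1))
    dE <- E[I] - E[1]
    f[I] <- if (dE > 0) oscillator_strength(dE, mu) else 0
  }

  lr_shifts <- numeric(n)
  if (!is.null(env) && include_lr && any(env$alphas > 0)) {
    for (I in 2:n) {
      tc <- source_charges(R, tq[1, I, ], "transition")
      lr_shifts[I] <- lr_environment_shift(tc, env, tol = tol)
    }
    E <- E + lr_shifts
    if (length(lr_gradient_states) > 0) {
      for (I in lr_gradient_states) {
        if (I == 1 || abs(lr_shifts[I]) < 1e-14) next
        G[I, , ] <- G[I, , ] +
          lr_shift_gradient(model, R, env, I, U, lr_step, tol)
      }
    }
  }

  structure(list(energies = E, U = U, gradients = G, f = f,
                 state_charges = sq, trans_charges = tq,
                 lr_shifts = lr_shifts, H = H, V_env = V_env),
            class = "electronic_result")
}

# central-difference gradient of the LR shift of state I w.r.t. the QM
# coordinates (eigenvectors at displaced geometries are phase-aligned to U)
lr_shift_gradient <- function(model, R, env, I, U_ref, step, tol) {
  shift_at <- function(Rx) {
    H <- diabatic_hamiltonian(model, Rx)
    V <- multipole_potential(env, Rx)
    for (k in seq_len(model$n_states))
      H[k, k] <- H[k, k] + sum(model$state_charges[k, ] * V)
    eig <- eigen(H, symmetric = TRUE)
    ord <- order(eig$values)
    Ux <- fix_phases(eig$vectors[, ord, drop = FALSE], U_ref)
    qt <- colSums(Ux[, 1] * Ux[, I] * model$trans_charges)
    lr_environment_shift(source_charges(Rx, qt, "transition"), env, tol = tol)
  }
  G <- matrix(0, model$n_atoms, 3)
  for (a in seq_len(model$n_atoms)) for (x in 1:3) {
    Rp <- R; Rp[a, x] <- Rp[a, x] + step
    Rm <- R; Rm[a, x] <- Rm[a, x] - step
    G[a, x] <- (shift_at(Rp) - shift_at(Rm)) / (2 * step)
  }
  G
}

#' @export
print.electronic_result <- function(x, ...) {
  n <- length(x$energies)
  cat("electronic_result:", n, "states\n")
  exc <- hartree_to_ev(x$energies - x$energies[1])
  cat("  excitations (eV):", paste(sprintf("%.3f", exc[-1]), collapse = " "), "\n")
  cat("  f:", paste(sprintf("%.4f", x$f[-1]), collapse = " "), "\n")
  invisible(x)
}

#' Oscillator strength from excitation energy and transition dipole
#'
#' \eqn{f = \tfrac23\,\Delta E\,|\mu_{tr}|^2} in atomic units.
#'
#' @param dE excitation energy (Hartree), must be positive.
#' @param mu_tr transition dipole vector (a.u.).
#' @return oscillator strength (dimensionless, >= 0).
#' @export
oscillator_strength <- function(dE, mu_tr) {
  if (dE <= 0) stop("oscillator_strength requires a positive excitation energy")
  (2 / 3) * dE * sum(mu_tr^2)
}
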