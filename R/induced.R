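# Coupled induced-dipole equations (alpha^-1 - T) mu = E, solved by a
# diagonally preconditioned conjugate gradient, plus the polarization,
# linear-response (LR) and corrected-linear-response (cLR) energy terms.

# Build the polarization system matrix over the alpha > 0 sites.
polarization_matrix <- function(m) {
  idx <- which(m$alphas > 0)
  np <- length(idx)
  if (np == 0) return(list(idx = idx, A = NULL))
  if (np == 1) {
    A <- diag(3) / m$alphas[idx]
  } else {
    T <- dipole_interaction_tensor(m$positions[idx, , drop = FALSE],
                                   damping = m$damping,
                                   alphas = m$alphas[idx])
    A <- diag(rep(1 / m$alphas[idx], each = 3)) - T
  }
  list(idx = idx, A = A)
}

# Preconditioned conjugate gradient for the SPD polarization system.
# M^-1 is the per-site polarizability (inverse of the diagonal blocks).
pcg_solve <- function(A, b, precond, tol = 1e-8, max_iter = 500L) {
  x <- precond * b  # alpha * E: the uncoupled guess
  r <- b - as.numeric(A %*% x)
  z <- precond * r
  p <- z
  rz <- sum(r * z)
  iter <- 0L
  while (sqrt(sum(r * r)) > tol && iter < max_iter) {
    Ap <- as.numeric(A %*% p)
    curv <- sum(p * Ap)
    if (curv <= 0)
      stop("PCG breakdown: non-positive curvature; the polarization system ",
           "is not positive definite (reduce polarizabilities, separate ",
           "sites, or enable Thole damping)")
    a <- rz / curv
    x <- x + a * p
    r <- r - a * Ap
    z <- precond * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    iter <- iter + 1L
  }
  res <- sqrt(sum(r * r))
  if (res > tol)
    stop("PCG did not converge in ", max_iter,
         " iterations (residual ", format(res), ")")
  list(x = x, residual = res, iterations = iter)
}

#' Solve the coupled induced-dipole equations
#'
#' Solves \eqn{(\alpha^{-1} - T)\,\mu = E} for the two induced-dipole sets
#' \eqn{\mu_d} (driven by `E_d`) and \eqn{\mu_p} (driven by `E_p`) over the
#' polarizable (alpha > 0) sites of `m`, using a preconditioned conjugate
#' gradient with the per-site polarizability as preconditioner.
#'
#' @param m a `multipole_set`.
#' @param E_p,E_d n x 3 field matrices at all sites of `m` (only polarizable
#'   rows are used), e.g. from [static_fields()].
#' @param tol residual-norm convergence threshold (a.u.), default 1e-8.
#' @param max_iter maximum PCG iterations.
#' @return an `induced_dipole_pair`: matrices `mu_d`, `mu_p` (rows follow
#'   `pol_idx`, the indices of polarizable sites), the driving fields, the
#'   residual norms and the tolerance they were converged to.
#' @export
solve_induced_dipoles <- function(m, E_p, E_d, tol = 1e-8, max_iter = 500L) {
  pm <- polarization_matrix(m)
  idx <- pm$idx
  np <- length(idx)
  if (np == 0) {
    return(structure(list(mu_d = matrix(0, 0, 3), mu_p = matrix(0, 0, 3),
                          E_d = matrix(0, 0, 3), E_p = matrix(0, 0, 3),
                          residuals = c(d = 0, p = 0), tol = tol,
                          pol_idx = idx),
                     class = "induced_dipole_pair"))
  }
  Ep <- matrix(E_p, ncol = 3)[idx, , drop = FALSE]
  Ed <- matrix(E_d, ncol = 3)[idx, , drop = FALSE]
  precond <- rep(m$alphas[idx], each = 3)
  to_vec <- function(M) as.numeric(t(M))
  to_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  sol_d <- pcg_solve(pm$A, to_vec(Ed), precond, tol, max_iter)
  sol_p <- pcg_solve(pm$A, to_vec(Ep), precond, tol, max_iter)
  structure(list(mu_d = to_mat(sol_d$x), mu_p = to_mat(sol_p$x),
                 E_d = Ed, E_p = Ep,
                 residuals = c(d = sol_d$residual, p = sol_p$residual),
                 tol = tol, pol_idx = idx),
            class = "induced_dipole_pair")
}

#' @export
print.induced_dipole_pair <- function(x, ...) {
  cat("induced_dipole_pair:", nrow(x$mu_d), "polarizable sites; residuals",
      format(x$residuals["d"]), "/", format(x$residuals["p"]), "\n")
  invisible(x)
}

#' Polarization energy of a converged induced-dipole pair
#'
#' At stationarity of the dual-set polarization Lagrangian the energy is
#' \eqn{-\tfrac12 \langle \mu_d, E_p\rangle} (equal to
#' \eqn{-\tfrac12\langle\mu_p, E_d\rangle} by symmetry of the system matrix).
#'
#' @param pair an `induced_dipole_pair` from [solve_induced_dipoles()].
#' @return polarization energy (Hartree); non-positive when `E_p = E_d`.
#' @export
polarization_energy <- function(pair) {
  -0.5 * sum(pair$mu_d * pair$E_p)
}

#' Linear-response environment shift of an excitation energy
#'
#' The instantaneous response of the polarizable sites to a transition
#' density: the field `E` of the transition charges is computed at the
#' polarizable sites, the induced dipoles `mu` are solved for, and the shift
#' \eqn{-\langle \mu, E\rangle} is returned. Non-positive for a
#' positive-definite response.
#'
#' @param tc `source_charges` of kind `"transition"`.
#' @param m a `multipole_set` supplying positions and polarizabilities.
#' @param tol PCG tolerance.
#' @return energy shift (Hartree).
#' @export
lr_environment_shift <- function(tc, m, tol = 1e-8) {
  if (!inherits(tc, "source_charges") || tc$kind != "transition")
    stop("lr_environment_shift expects transition-density source charges")
  response_energy(tc, m, tol, half = FALSE)
}

#' Corrected-linear-response (state-specific) energy correction
#'
#' The a-posteriori state-specific correction \eqn{-\tfrac12\langle
#' \mu^\Delta, E^\Delta\rangle}, with \eqn{E^\Delta} the field of the
#' ground-to-excited difference-density charges and \eqn{\mu^\Delta} the
#' dipoles it induces. Additive to LR excitation energies; it never feeds
#' back into the dynamics.
#'
#' @param dd `source_charges` of kind `"difference"`.
#' @param m a `multipole_set`.
#' @param tol PCG tolerance.
#' @return energy correction (Hartree).
#' @export
clr_correction <- function(dd, m, tol = 1e-8) {
  if (!inherits(dd, "source_charges") || dd$kind != "difference")
    stop("clr_correction expects difference-density source charges")
  response_energy(dd, m, tol, half = TRUE)
}

response_energy <- function(src, m, tol, half) {
  if (all(m$alphas == 0) || all(src$values == 0)) return(0)
  E <- field_of_charges(src$positions, src$values, m$positions)
  pair <- solve_induced_dipoles(m, E, E, tol = tol)
  e <- -sum(pair$mu_d * pair$E_d)
  if (half) e / 2 else e
}
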