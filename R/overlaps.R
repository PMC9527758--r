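# Overlaps between auxiliary excited-state wavefunctions at successive time
# steps and the Hammes-Schiffer--Tully (HST) finite-difference estimate of
# the time-derivative nonadiabatic coupling. Auxiliary wavefunctions are
# normalized sums of singly excited determinants with CIS-like coefficients;
# spin orbitals are treated explicitly.

#' Construct a single-excitation (Casida-type) expansion
#'
#' @param C AO x MO coefficient matrix (spin orbitals as columns).
#' @param n_occ number of occupied spin orbitals (reference determinant =
#'   first `n_occ` columns).
#' @param coeffs list of per-state coefficient matrices `c[i, a]`
#'   (`n_occ x n_virt`); they are normalized internally so that the stored
#'   normalization factors satisfy \eqn{N_I = (\sum |c|^2)^{-1/2}}.
#' @return an object of class `casida_expansion` with fields `C`, `n_occ`,
#'   `coeffs`, `norms`.
#' @export
casida_expansion <- function(C, n_occ, coeffs) {
  C <- as.matrix(C)
  if (n_occ < 1 || n_occ > ncol(C)) stop("invalid occupied count")
  n_virt <- ncol(C) - n_occ
  coeffs <- lapply(coeffs, function(cc) {
    cc <- matrix(cc, n_occ, n_virt)
    cc
  })
  norms <- vapply(coeffs, function(cc) {
    s <- sum(cc^2)
    if (s <= 0) stop("excitation coefficients are all zero")
    1 / sqrt(s)
  }, numeric(1))
  structure(list(C = C, n_occ = n_occ, coeffs = coeffs, norms = norms),
            class = "casida_expansion")
}

#' Overlap between two Slater determinants
#'
#' Determinant of the mixed molecular-orbital overlap
#' \eqn{C_{bra}^T S_{AO} C_{ket}} restricted to the occupied columns.
#'
#' @param C_bra,C_ket AO x n_el matrices of occupied (spin) orbitals.
#' @param S_AO square symmetric atomic-orbital overlap matrix.
#' @return scalar overlap.
#' @export
determinant_overlap <- function(C_bra, C_ket, S_AO) {
  C_bra <- as.matrix(C_bra); C_ket <- as.matrix(C_ket)
  if (ncol(C_bra) != ncol(C_ket))
    stop("electron counts differ between bra and ket")
  if (nrow(C_bra) != nrow(S_AO) || nrow(C_ket) != ncol(S_AO))
    stop("AO dimension mismatch")
  det(crossprod(C_bra, S_AO %*% C_ket))
}

# occupied orbital set of the reference with column i replaced by virtual a
substitute_orbital <- function(C, n_occ, i, a) {
  occ <- C[, seq_len(n_occ), drop = FALSE]
  occ[, i] <- C[, n_occ + a]
  occ
}

#' State overlap matrix between successive steps
#'
#' Overlap matrix `S[I, J]` between the electronic states of expansion `a`
#' (bra, time t) and `b` (ket, time t + dt), including the closed-shell
#' reference as state index 1. The `"determinant"` route evaluates every
#' determinant pair \eqn{\langle\Phi_i^a|\Phi_j^b\rangle} exactly; the
#' `"orbital"` route keeps only products with a single substituted-orbital
#' overlap around the diagonal reference product (first-order in the MO
#' rotation between steps, with second-order error).
#'
#' @param a,b `casida_expansion` objects with equal AO dimension and
#'   electron count.
#' @param S_AO AO overlap matrix between the two steps (bra AOs x ket AOs).
#' @param method `"determinant"` or `"orbital"`.
#' @param dt time separation (a.u.) recorded in the result.
#' @return a `step_overlap`: list with matrix `S` ((n_states+1) square) and `dt`.
#' @export
state_overlap <- function(a, b, S_AO, method = c("determinant", "orbital"),
                          dt = 1) {
  method <- match.arg(method)
  if (a$n_occ != b$n_occ) stop("electron counts differ")
  if (nrow(a$C) != nrow(S_AO) || nrow(b$C) != ncol(S_AO))
    stop("AO dimension mismatch")
  n_occ <- a$n_occ
  n_virt_a <- ncol(a$C) - n_occ
  n_virt_b <- ncol(b$C) - n_occ
  ns_a <- length(a$coeffs); ns_b <- length(b$coeffs)
  S_mo <- crossprod(a$C, S_AO %*% b$C)
  occ <- seq_len(n_occ)
  S <- matrix(0, ns_a + 1, ns_b + 1)

  if (method == "determinant") {
    # <ref(t) | Phi_j^b(t+dt)> and transposes via explicit determinants
    det_sub <- function(i, ia, j, jb) {
      # i/ia: bra substitution (0 = none); j/jb: ket substitution
      rows <- occ; cols <- occ
      M <- S_mo[rows, cols, drop = FALSE]
      if (i > 0) M[i, ] <- S_mo[n_occ + ia, cols]
      if (j > 0) M[, j] <- S_mo[rows, n_occ + jb]
      if (i > 0 && j > 0) M[i, j] <- S_mo[n_occ + ia, n_occ + jb]
      det(M)
    }
    S[1, 1] <- det_sub(0, 0, 0, 0)
    for (J in seq_len(ns_b)) {
      cb <- b$coeffs[[J]]
      acc <- 0
      for (j in occ) for (bb in seq_len(n_virt_b)) {
        if (cb[j, bb] == 0) next
        acc <- acc + cb[j, bb] * det_sub(0, 0, j, bb)
      }
      S[1, J + 1] <- b$norms[J] * acc
    }
    for (I in seq_len(ns_a)) {
      ca <- a$coeffs[[I]]
      acc <- 0
      for (i in occ) for (aa in seq_len(n_virt_a)) {
        if (ca[i, aa] == 0) next
        acc <- acc + ca[i, aa] * det_sub(i, aa, 0, 0)
      }
      S[I + 1, 1] <- a$norms[I] * acc
      for (J in seq_len(ns_b)) {
        cb <- b$coeffs[[J]]
        acc <- 0
        for (i in occ) for (aa in seq_len(n_virt_a)) {
          if (ca[i, aa] == 0) next
          for (j in occ) for (bb in seq_len(n_virt_b)) {
            if (cb[j, bb] == 0) next
            acc <- acc + ca[i, aa] * cb[j, bb] * det_sub(i, aa, j, bb)
          }
        }
        S[I + 1, J + 1] <- a$norms[I] * b$norms[J] * acc
      }
    }
  } else {
    D0 <- det(S_mo[occ, occ, drop = FALSE])
    dref <- diag(S_mo)[occ]
    virt_a <- n_occ + seq_len(n_virt_a)
    virt_b <- n_occ + seq_len(n_virt_b)
    S[1, 1] <- D0
    for (J in seq_len(ns_b)) {
      cb <- b$coeffs[[J]]
      S[1, J + 1] <- b$norms[J] *
        sum(cb * (D0 / dref) * S_mo[occ, virt_b, drop = FALSE])
    }
    for (I in seq_len(ns_a)) {
      ca <- a$coeffs[[I]]
      S[I + 1, 1] <- a$norms[I] *
        sum(ca * (D0 / dref) * t(S_mo[virt_a, occ, drop = FALSE]))
      for (J in seq_len(ns_b)) {
        cb <- b$coeffs[[J]]
        acc <- 0
        for (i in occ) for (aa in seq_len(n_virt_a)) {
          if (ca[i, aa] == 0) next
          # same hole: reference factor times virtual-virtual overlap
          acc <- acc + ca[i, aa] * (D0 / dref[i]) *
            sum(cb[i, ] * S_mo[n_occ + aa, virt_b])
          # same particle, different hole: one occupied-occupied crossing
          for (j in occ) {
            if (j == i || aa > n_virt_b) next
            if (cb[j, aa] == 0) next
            acc <- acc - ca[i, aa] * cb[j, aa] *
              (D0 / (dref[i] * dref[j])) * S_mo[j, i] *
              S_mo[n_occ + aa, n_occ + aa]
          }
        }
        S[I + 1, J + 1] <- a$norms[I] * b$norms[J] * acc
      }
    }
  }
  structure(list(S = S, dt = dt), class = "step_overlap")
}

#' State overlap for the built-in diabatic-model backend
#'
#' For a fixed orthonormal diabatic basis the state overlap between steps is
#' exactly \eqn{S = U(t)^T U(t+\Delta t)}. Columns of the later step are
#' sign-aligned so that the diagonal is positive (phase tracking); diagonal
#' entries below 0.5 are reported via the `trivial_crossing` attribute.
#'
#' @param U_t,U_tdt orthogonal eigenvector matrices at t and t + dt.
#' @param dt time separation (a.u.).
#' @return a `step_overlap` (with `trivial_crossing` logical attribute).
#' @export
model_state_overlap <- function(U_t, U_tdt, dt = 1) {
  S <- crossprod(U_t, U_tdt)
  for (j in seq_len(ncol(S)))
    if (S[j, j] < 0) S[, j] <- -S[, j]
  out <- structure(list(S = S, dt = dt), class = "step_overlap")
  attr(out, "trivial_crossing") <- any(abs(diag(S)) < 0.5)
  out
}

#' @export
print.step_overlap <- function(x, ...) {
  cat("step_overlap:", nrow(x$S), "states, dt =", x$dt, "a.u.\n")
  invisible(x)
}

#' HST time-derivative nonadiabatic coupling
#'
#' Finite-difference estimate
#' \eqn{\sigma_{IJ} = (S_{IJ} - S_{JI})/(2\Delta t)} from a step-overlap
#' matrix; antisymmetric with zero diagonal by construction, second-order
#' accurate in \eqn{\Delta t}.
#'
#' @param S a `step_overlap` (or plain square matrix, then `dt` is required).
#' @param dt time step (a.u.); defaults to the value stored in `S`.
#' @return antisymmetric coupling matrix (a.u.^-1).
#' @export
hst_coupling <- function(S, dt = NULL) {
  if (inherits(S, "step_overlap")) {
    if (is.null(dt)) dt <- S$dt
    S <- S$S
  }
  if (is.null(dt) || dt <= 0) stop("dt must be positive")
  (S - t(S)) / (2 * dt)
}
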