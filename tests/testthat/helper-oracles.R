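# Shared fixtures and independent oracles used across the suite.

# random multipole set with well-separated sites
random_multipole_set <- function(n, seed = 1, with_dipoles = TRUE,
                                 with_quads = TRUE, alpha_max = 2,
                                 box = 12) {
  set.seed(seed)
  repeat {
    pos <- matrix(runif(n * 3, -box / 2, box / 2), n, 3)
    if (n < 2 || min(dist(pos)) > 3) break
  }
  dip <- if (with_dipoles) matrix(rnorm(n * 3, sd = 0.3), n, 3) else NULL
  quads <- NULL
  if (with_quads) {
    quads <- array(0, c(n, 3, 3))
    for (i in seq_len(n)) {
      m <- matrix(rnorm(9, sd = 0.2), 3, 3)
      m <- (m + t(m)) / 2
      quads[i, , ] <- m - diag(3) * sum(diag(m)) / 3
    }
  }
  multipole_set(pos, charges = rnorm(n, sd = 0.5), dipoles = dip,
                quadrupoles = quads, alphas = runif(n, 0.1, alpha_max))
}

# naive per-pair field summation: independent scalar-math implementation
brute_force_fields <- function(m) {
  n <- nrow(m$positions)
  E <- matrix(0, n, 3)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- m$positions[i, ] - m$positions[j, ]
    d <- sqrt(sum(r^2))
    # charge
    E[i, ] <- E[i, ] + m$charges[j] * r / d^3
    # dipole: (3 (mu.rh) rh - mu)/d^3
    mu <- m$dipoles[j, ]
    rh <- r / d
    E[i, ] <- E[i, ] + (3 * sum(mu * rh) * rh - mu) / d^3
    # traceless quadrupole with V = r'Tr/(2 d^5): E = 5r(r'Tr)/(2d^7) - Tr/d^5
    th <- m$quadrupoles[j, , ]
    tr <- as.numeric(th %*% r)
    E[i, ] <- E[i, ] + 5 * r * sum(r * tr) / (2 * d^7) - tr / d^5
  }
  E
}

# dense direct solve of the polarization equations
dense_dipole_solve <- function(m, E) {
  idx <- which(m$alphas > 0)
  T <- dipole_interaction_tensor(m$positions[idx, , drop = FALSE])
  A <- diag(rep(1 / m$alphas[idx], each = 3)) - T
  mu <- solve(A, as.numeric(t(matrix(E, ncol = 3)[idx, , drop = FALSE])))
  matrix(mu, ncol = 3, byrow = TRUE)
}

proper_rotation <- function(seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Leibniz permutation-sum determinant: independent oracle for determinant
# overlaps (n <= 5)
permanent_style_det <- function(M) {
  n <- nrow(M)
  perms <- all_permutations(n)
  s <- 0
  for (p in perms) {
    sgn <- permutation_sign(p)
    s <- s + sgn * prod(M[cbind(seq_len(n), p)])
  }
  s
}
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) for (k in seq_len(n)) {
    out[[length(out) + 1]] <- append(p, n, after = k - 1)
  }
  out
}
permutation_sign <- function(p) {
  n <- length(p)
  s <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (p[i] > p[j]) s <- -s
  s
}

# brute-force overlap of two excited determinants by explicit orbital-set
# expansion (independent of state_overlap internals)
brute_force_state_overlap <- function(a, b, S_AO) {
  n_occ <- a$n_occ
  nsa <- length(a$coeffs); nsb <- length(b$coeffs)
  S_mo <- t(a$C) %*% S_AO %*% b$C
  occ_det <- function(bra_cols, ket_cols) {
    M <- S_mo[bra_cols, ket_cols, drop = FALSE]
    permanent_style_det(M)
  }
  bra_sets <- list(seq_len(n_occ))
  ket_sets <- list(seq_len(n_occ))
  S <- matrix(0, nsa + 1, nsb + 1)
  S[1, 1] <- occ_det(seq_len(n_occ), seq_len(n_occ))
  subst <- function(i, a_virt) { s <- seq_len(n_occ); s[i] <- n_occ + a_virt; s }
  nva <- ncol(a$C) - n_occ; nvb <- ncol(b$C) - n_occ
  for (J in seq_len(nsb)) {
    acc <- 0
    for (j in seq_len(n_occ)) for (bb in seq_len(nvb))
      acc <- acc + b$coeffs[[J]][j, bb] * occ_det(seq_len(n_occ), subst(j, bb))
    S[1, J + 1] <- b$norms[J] * acc
  }
  for (I in seq_len(nsa)) {
    acc <- 0
    for (i in seq_len(n_occ)) for (aa in seq_len(nva))
      acc <- acc + a$coeffs[[I]][i, aa] * occ_det(subst(i, aa), seq_len(n_occ))
    S[I + 1, 1] <- a$norms[I] * acc
    for (J in seq_len(nsb)) {
      acc <- 0
      for (i in seq_len(n_occ)) for (aa in seq_len(nva))
        for (j in seq_len(n_occ)) for (bb in seq_len(nvb))
          acc <- acc + a$coeffs[[I]][i, aa] * b$coeffs[[J]][j, bb] *
            occ_det(subst(i, aa), subst(j, bb))
      S[I + 1, J + 1] <- a$norms[I] * b$norms[J] * acc
    }
  }
  S
}

# random orthonormal MO set (w.r.t. S_AO = I) plus a small rotation partner
random_casida_pair <- function(n_ao, n_occ, n_states, seed = 1,
                               rot_angle = 1e-3) {
  set.seed(seed)
  C <- qr.Q(qr(matrix(rnorm(n_ao * n_ao), n_ao, n_ao)))
  n_virt <- n_ao - n_occ
  # orthonormal excitation-coefficient vectors (CIS eigenvectors are
  # orthogonal; states of one expansion must be too)
  ortho_coeffs <- function(raw) {
    Q <- qr.Q(qr(raw))
    lapply(seq_len(ncol(Q)), function(I) matrix(Q[, I], n_occ, n_virt))
  }
  raw <- matrix(rnorm(n_occ * n_virt * n_states), n_occ * n_virt, n_states)
  coeffs <- ortho_coeffs(raw)
  a <- casida_expansion(C, n_occ, coeffs)
  # small orthogonal rotation of the MO space + small coefficient rotation
  G <- matrix(rnorm(n_ao * n_ao, sd = 1), n_ao, n_ao)
  G <- (G - t(G)) / 2
  Rot <- qr.Q(qr(diag(n_ao) + rot_angle * G))
  Rot <- Rot %*% diag(sign(diag(Rot)))  # near-identity orthogonal rotation
  C2 <- C %*% Rot
  raw2 <- raw + matrix(rnorm(length(raw), sd = rot_angle), nrow(raw))
  coeffs2 <- ortho_coeffs(raw2)
  b <- casida_expansion(C2, n_occ, coeffs2)
  list(a = a, b = b, S_AO = diag(n_ao))
}

# two-state eigenbasis rotating at constant angular rate; the convention is
# chosen so that U(0)' U(theta) = [[cos, sin], [-sin, cos]]
rotating_U <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
}

# scripted trajectory-like object for the event detectors
scripted_trajectory <- function(dist_ang_nh, dt_fs = 0.5, n_atoms = 3,
                                acceptor = 1, h = 2) {
  frames <- lapply(dist_ang_nh, function(d) {
    R <- matrix(0, n_atoms, 3)
    R[h, 3] <- ang_to_bohr(d)
    R
  })
  log <- data.frame(t_fs = seq_len(length(dist_ang_nh) - 1) * dt_fs)
  list(frames = frames, log = log, qm_mask = rep(TRUE, n_atoms))
}

edpt_efun <- function(fixture, ...) {
  function(R) evaluate_states(fixture$model, R, env = fixture$env, ...)
}
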