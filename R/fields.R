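# Electrostatic kernels: the dipole-dipole interaction tensor and the static
# fields / potentials of a multipolar distribution. Quadrupoles follow the
# traceless Buckingham convention with potential V = r' Theta r / (2 r^5).

#' Dipole-dipole interaction tensor
#'
#' Builds the full 3n x 3n interaction matrix whose off-diagonal 3x3 blocks
#' are \eqn{T_{ij} = (3 \hat r \hat r^T - I)/r^3} (optionally Thole-damped)
#' and whose diagonal blocks are zero. Contracting `T` with stacked dipoles
#' gives the field each dipole produces at every other site.
#'
#' @param positions n x 3 matrix of site positions (Bohr), n >= 2.
#' @param damping optional Thole exponential damping parameter `a`; `NULL`
#'   (default) for undamped tensors.
#' @param alphas optional polarizabilities (Bohr^3) used to build the Thole
#'   scaled distance \eqn{u = r/(\alpha_i\alpha_j)^{1/6}}; required when
#'   `damping` is given.
#' @return a 3n x 3n symmetric numeric matrix.
#' @export
dipole_interaction_tensor <- function(positions, damping = NULL, alphas = NULL) {
  positions <- as_position_matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 sites")
  if (!is.null(damping) && is.null(alphas))
    stop("Thole damping requires site polarizabilities")
  T <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- positions[i, ] - positions[j, ]
      d <- sqrt(sum(r * r))
      if (d < 1e-10)
        stop("coincident sites ", i, " and ", j)
      rh <- r / d
      l3 <- 1; l5 <- 1
      if (!is.null(damping) && alphas[i] > 0 && alphas[j] > 0) {
        u <- d / (alphas[i] * alphas[j])^(1 / 6)
        au3 <- damping * u^3
        l3 <- 1 - exp(-au3)
        l5 <- 1 - (1 + au3) * exp(-au3)
      }
      blk <- (3 * l5 * tcrossprod(rh) - l3 * diag(3)) / d^3
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      T[ii, jj] <- blk
      T[jj, ii] <- blk  # r -> -r leaves the block unchanged
    }
  }
  T
}

# Field at `at` (m x 3) from point charges: E = q (r_at - r_src)/|.|^3.
# Pairs with distance < eps are skipped (self-interaction guard).
field_of_charges <- function(src_pos, src_q, at, eps = 1e-10) {
  at <- as_position_matrix(at)
  src_pos <- as_position_matrix(src_pos)
  E <- matrix(0, nrow(at), 3)
  for (j in seq_along(src_q)) {
    if (src_q[j] == 0) next
    dr <- sweep(at, 2, src_pos[j, ])
    d2 <- rowSums(dr * dr)
    ok <- d2 > eps^2
    E[ok, ] <- E[ok, ] + src_q[j] * dr[ok, , drop = FALSE] / d2[ok]^1.5
  }
  E
}

# Field at one point from one static dipole/quadrupole at src.
field_of_dipole <- function(src, mu, at) {
  r <- at - src
  d <- sqrt(sum(r * r))
  rh <- r / d
  (3 * sum(rh * mu) * rh - mu) / d^3
}

field_of_quadrupole <- function(src, theta, at) {
  r <- at - src
  d <- sqrt(sum(r * r))
  tr <- as.numeric(theta %*% r)
  (5 / 2) * r * sum(r * tr) / d^7 - tr / d^5
}

#' Electrostatic potential of a multipole set
#'
#' Potential of the static multipoles of `m` evaluated at arbitrary points
#' (used to couple environment electrostatics to model state charges).
#' Sources closer than `eps` to an evaluation point are skipped.
#'
#' @param m a `multipole_set`.
#' @param at k x 3 matrix of evaluation points (Bohr).
#' @param eps self-interaction cutoff distance (Bohr).
#' @return numeric vector of potentials (a.u.).
#' @export
multipole_potential <- function(m, at, eps = 1e-10) {
  at <- as_position_matrix(at)
  V <- numeric(nrow(at))
  for (j in seq_len(n_sites(m))) {
    dr <- sweep(at, 2, m$positions[j, ])
    d <- sqrt(rowSums(dr * dr))
    ok <- d > eps
    if (!any(ok)) next
    V[ok] <- V[ok] + m$charges[j] / d[ok]
    mu <- m$dipoles[j, ]
    if (any(mu != 0))
      V[ok] <- V[ok] + (dr[ok, , drop = FALSE] %*% mu) / d[ok]^3
    th <- m$quadrupoles[j, , ]
    if (any(th != 0)) {
      rt <- dr[ok, , drop = FALSE] %*% th
      V[ok] <- V[ok] + rowSums(rt * dr[ok, , drop = FALSE]) / (2 * d[ok]^5)
    }
  }
  V
}

# Field of all static multipoles of m at arbitrary points (no exclusions).
multipole_field_at <- function(m, at, eps = 1e-10) {
  at <- as_position_matrix(at)
  E <- field_of_charges(m$positions, m$charges, at, eps)
  for (j in seq_len(n_sites(m))) {
    mu <- m$dipoles[j, ]; th <- m$quadrupoles[j, , ]
    if (all(mu == 0) && all(th == 0)) next
    for (i in seq_len(nrow(at))) {
      d <- sqrt(sum((at[i, ] - m$positions[j, ])^2))
      if (d <= eps) next
      if (any(mu != 0)) E[i, ] <- E[i, ] + field_of_dipole(m$positions[j, ], mu, at[i, ])
      if (any(th != 0)) E[i, ] <- E[i, ] + field_of_quadrupole(m$positions[j, ], th, at[i, ])
    }
  }
  E
}

#' Static induction fields at the polarizable sites
#'
#' Assembles the two static fields `E_p` and `E_d` produced by the multipolar
#' distribution (and an optional external point-charge source) at every site
#' of `m`. The two fields differ only through the exclusion-pair lists and
#' scale factors stored in `m`; with empty lists they are identical. A site
#' never sees its own multipoles.
#'
#' @param m a `multipole_set`.
#' @param extra optional `source_charges` whose field is added to both sets.
#' @return list with n x 3 matrices `E_p` and `E_d`.
#' @export
static_fields <- function(m, extra = NULL) {
  n <- n_sites(m)
  E <- matrix(0, n, 3)
  # pairwise static field of site j at site i (both directions)
  pair_field <- function(i, j) {
    at <- m$positions[i, ]
    src <- m$positions[j, ]
    r <- at - src
    d <- sqrt(sum(r * r))
    out <- m$charges[j] * r / d^3
    mu <- m$dipoles[j, ]
    if (any(mu != 0)) out <- out + field_of_dipole(src, mu, at)
    th <- m$quadrupoles[j, , ]
    if (any(th != 0)) out <- out + field_of_quadrupole(src, th, at)
    out
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    E[i, ] <- E[i, ] + pair_field(i, j)
  }
  apply_exclusions <- function(E, ex) {
    if (nrow(ex$pairs) == 0) return(E)
    for (k in seq_len(nrow(ex$pairs))) {
      i <- ex$pairs[k, 1]; j <- ex$pairs[k, 2]; s <- ex$scale[k]
      E[i, ] <- E[i, ] - (1 - s) * pair_field(i, j)
      E[j, ] <- E[j, ] - (1 - s) * pair_field(j, i)
    }
    E
  }
  E_p <- apply_exclusions(E, m$exclude_p)
  E_d <- apply_exclusions(E, m$exclude_d)
  if (!is.null(extra)) {
    Ex <- field_of_charges(extra$positions, extra$values, m$positions)
    E_p <- E_p + Ex
    E_d <- E_d + Ex
  }
  list(E_p = E_p, E_d = E_d)
}
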