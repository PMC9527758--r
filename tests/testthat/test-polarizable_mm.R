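# Electrostatics and the coupled induced-dipole machinery.

test_that("dipole interaction tensor matches the closed-form axial block", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 1))
  T <- dipole_interaction_tensor(pos)
  blk <- T[1:3, 4:6]
  expect_equal(blk, diag(c(-1, -1, 2)), tolerance = 1e-14)
  expect_equal(T[4:6, 1:3], t(blk), tolerance = 1e-14)
  # decay limit
  far <- dipole_interaction_tensor(rbind(c(0, 0, 0), c(0, 0, 1e4)))
  expect_lt(max(abs(far)), 1e-11)
})

test_that("tensor contraction reproduces brute-force point-dipole fields", {
  set.seed(4)
  n <- 5
  pos <- matrix(runif(n * 3, -6, 6), n, 3)
  while (min(dist(pos)) < 2) pos <- matrix(runif(n * 3, -6, 6), n, 3)
  mu <- matrix(rnorm(n * 3), n, 3)
  T <- dipole_interaction_tensor(pos)
  E_tensor <- matrix(T %*% as.numeric(t(mu)), ncol = 3, byrow = TRUE)
  for (i in seq_len(n)) {
    E_ref <- c(0, 0, 0)
    for (j in seq_len(n)) {
      if (j == i) next
      r <- pos[i, ] - pos[j, ]
      d <- sqrt(sum(r^2)); rh <- r / d
      E_ref <- E_ref + (3 * sum(rh * mu[j, ]) * rh - mu[j, ]) / d^3
    }
    expect_equal(E_tensor[i, ], E_ref, tolerance = 1e-12)
  }
})

test_that("coincident sites raise an error naming the pair", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_error(dipole_interaction_tensor(pos), "2 and 3")
})

test_that("static fields: Coulomb law, exclusion symmetry, brute-force match", {
  m <- multipole_set(rbind(c(0, 0, 0), c(0, 0, 1)), charges = c(1, 0),
                     alphas = c(0, 1))
  f <- static_fields(m)
  expect_equal(f$E_p[2, ], c(0, 0, 1), tolerance = 1e-14)
  expect_identical(f$E_p, f$E_d)  # empty exclusion lists

  m6 <- random_multipole_set(6, seed = 11)
  f6 <- static_fields(m6)
  E_ref <- brute_force_fields(m6)
  expect_equal(f6$E_p, E_ref, tolerance = 1e-11)
  expect_equal(f6$E_d, E_ref, tolerance = 1e-11)

  # an excluded pair removes exactly its pairwise contribution from E_p only
  m_ex <- multipole_set(m6$positions, m6$charges, m6$dipoles, m6$quadrupoles,
                        m6$alphas, exclude_p = rbind(c(1, 2)))
  f_ex <- static_fields(m_ex)
  expect_equal(f_ex$E_d, E_ref, tolerance = 1e-11)
  expect_false(isTRUE(all.equal(f_ex$E_p[1, ], E_ref[1, ], tolerance = 1e-8)))
  expect_equal(f_ex$E_p[3:6, ], E_ref[3:6, ], tolerance = 1e-11)
})

test_that("quadrupole field is the negative gradient of its potential", {
  m <- random_multipole_set(2, seed = 3, with_dipoles = FALSE)
  m$charges[] <- 0
  at <- c(1.5, -2.0, 3.0)
  E <- polhop:::multipole_field_at(m, matrix(at, 1))
  h <- 1e-5
  E_num <- vapply(1:3, function(k) {
    dp <- at; dm <- at
    dp[k] <- dp[k] + h; dm[k] <- dm[k] - h
    -(multipole_potential(m, matrix(dp, 1)) -
        multipole_potential(m, matrix(dm, 1))) / (2 * h)
  }, numeric(1))
  expect_equal(as.numeric(E), E_num, tolerance = 1e-8)
})

test_that("induced-dipole solver: single-site limits and dense-solve match", {
  m1 <- multipole_set(matrix(c(0, 0, 0), 1), alphas = 2)
  E <- matrix(c(0, 0, 0.5), 1)
  pair <- solve_induced_dipoles(m1, E, E)
  expect_equal(pair$mu_d[1, ], c(0, 0, 1), tolerance = 1e-12)
  zero <- solve_induced_dipoles(m1, 0 * E, 0 * E)
  expect_equal(zero$mu_d, matrix(0, 1, 3))

  m8 <- random_multipole_set(8, seed = 21)
  f <- static_fields(m8)
  pair8 <- solve_induced_dipoles(m8, f$E_p, f$E_d, tol = 1e-12)
  mu_ref <- dense_dipole_solve(m8, f$E_d)
  expect_lt(max(abs(pair8$mu_d - mu_ref)) / max(abs(mu_ref)), 1e-10)
  expect_true(all(pair8$residuals <= 1e-12))
})

test_that("solver errors are informative", {
  m <- random_multipole_set(4, seed = 2)
  f <- static_fields(m)
  expect_error(solve_induced_dipoles(m, f$E_p, f$E_d, tol = 1e-15,
                                     max_iter = 1L),
               "did not converge")
  # overlapping high-polarizability sites break positive definiteness
  m_bad <- multipole_set(rbind(c(0, 0, 0), c(0, 0, 1.2)), alphas = c(8, 8))
  f <- list(E = matrix(1, 2, 3))
  expect_error(solve_induced_dipoles(m_bad, f$E, f$E), "positive definite")
})

test_that("polarization energy: closed forms and Lagrangian minimum", {
  m1 <- multipole_set(matrix(0, 1, 3), alphas = 1)
  E <- matrix(c(0, 0, 1), 1)
  pair <- solve_induced_dipoles(m1, E, E)
  expect_equal(polarization_energy(pair), -0.5, tolerance = 1e-12)
  zero <- solve_induced_dipoles(m1, 0 * E, 0 * E)
  expect_equal(polarization_energy(zero), 0)

  # numerical minimization of the explicit quadratic functional over mu
  m5 <- random_multipole_set(5, seed = 31, alpha_max = 1.5)
  f <- static_fields(m5)
  pair5 <- solve_induced_dipoles(m5, f$E_p, f$E_d, tol = 1e-12)
  idx <- which(m5$alphas > 0)
  T <- dipole_interaction_tensor(m5$positions[idx, , drop = FALSE])
  A <- diag(rep(1 / m5$alphas[idx], each = 3)) - T
  b <- as.numeric(t(f$E_p[idx, , drop = FALSE]))
  lagr <- function(mu) 0.5 * sum(mu * (A %*% mu)) - sum(mu * b)
  opt <- optim(rep(0, length(b)), lagr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_equal(polarization_energy(pair5), opt$value, tolerance = 1e-7)
})

test_that("polarization energy is invariant under rigid rotation+translation", {
  m <- random_multipole_set(6, seed = 41)
  Q <- proper_rotation(7)
  shift <- c(3, -2, 5)
  rot_quads <- m$quadrupoles
  for (i in seq_len(6)) rot_quads[i, , ] <- Q %*% m$quadrupoles[i, , ] %*% t(Q)
  m_rot <- multipole_set(sweep(m$positions %*% t(Q), 2, -shift),
                         m$charges, m$dipoles %*% t(Q), rot_quads, m$alphas)
  e1 <- polarization_energy(do.call(solve_induced_dipoles,
          c(list(m), static_fields(m), tol = 1e-12)))
  e2 <- polarization_energy(do.call(solve_induced_dipoles,
          c(list(m_rot), static_fields(m_rot), tol = 1e-12)))
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("single-site response is linear in alpha", {
  E <- matrix(c(0.2, -0.1, 0.4), 1)
  for (a in c(0.7, 1.4)) {
    m <- multipole_set(matrix(0, 1, 3), alphas = a)
    pair <- solve_induced_dipoles(m, E, E)
    expect_equal(sqrt(sum(pair$mu_d^2)), a * sqrt(sum(E^2)), tolerance = 1e-12)
    expect_equal(polarization_energy(pair), -0.5 * a * sum(E^2),
                 tolerance = 1e-12)
  }
})

test_that("LR shift: trivial zeros and single-site closed form", {
  m <- multipole_set(matrix(c(5, 0, 0), 1), alphas = 1.3)
  tc0 <- source_charges(rbind(c(0, 0, 0), c(0, 0, 0.5)), c(0, 0), "transition")
  expect_equal(lr_environment_shift(tc0, m), 0)
  m0 <- multipole_set(matrix(c(5, 0, 0), 1), alphas = 0)
  tc <- source_charges(rbind(c(0, 0, 0.25), c(0, 0, -0.25)), c(0.3, -0.3),
                       "transition")
  expect_equal(lr_environment_shift(tc, m0), 0)
  # one transition-dipole source near one polarizable site: -alpha E^2
  E <- polhop:::field_of_charges(tc$positions, tc$values, m$positions)
  expect_equal(lr_environment_shift(tc, m), -1.3 * sum(E^2),
               tolerance = 1e-10)
  expect_lt(lr_environment_shift(tc, m), 0)
  expect_error(lr_environment_shift(source_charges(matrix(0, 1, 3), 1, "state"), m),
               "transition")
})

test_that("cLR correction: zeros, closed form, sign", {
  m <- multipole_set(matrix(c(4, 1, 0), 1), alphas = 0.9)
  dd0 <- source_charges(matrix(0, 1, 3), 0, "difference")
  expect_equal(clr_correction(dd0, m), 0)
  dd <- source_charges(rbind(c(0, 0, 0), c(1, 0, 0)), c(0.4, -0.4),
                       "difference")
  E <- polhop:::field_of_charges(dd$positions, dd$values, m$positions)
  expect_equal(clr_correction(dd, m), -0.5 * 0.9 * sum(E^2), tolerance = 1e-10)
  m0 <- multipole_set(matrix(c(4, 1, 0), 1), alphas = 0)
  expect_equal(clr_correction(dd, m0), 0)
  expect_error(clr_correction(source_charges(matrix(0, 1, 3), 1, "transition"), m),
               "difference")
})

test_that("LR shift and cLR are non-positive on random polarizable systems", {
  for (seed in 1:4) {
    m <- random_multipole_set(7, seed = 100 + seed, alpha_max = 1.2)
    set.seed(seed)
    q <- rnorm(4); q <- q - mean(q)
    pos <- matrix(rnorm(12, sd = 0.8), 4, 3)
    expect_lte(lr_environment_shift(source_charges(pos, q, "transition"), m), 0)
    expect_lte(clr_correction(source_charges(pos, q + 0.1, "difference"), m), 0)
  }
})

test_that("multipole_set validates its invariants", {
  expect_error(multipole_set(matrix(0, 1, 3), alphas = -1), ">= 0")
  q <- array(0, c(1, 3, 3)); q[1, , ] <- diag(3)
  expect_error(multipole_set(matrix(0, 1, 3), quadrupoles = q), "traceless")
  m <- multipole_set(rbind(c(0, 0, 0), c(0, 0, 3)),
                     exclude_p = rbind(c(1, 2), c(2, 1)))
  expect_equal(nrow(m$exclude_p$pairs), 1)  # stored symmetrically, once
})
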