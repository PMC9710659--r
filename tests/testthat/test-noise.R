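test_that("PSD projection fixes non-Euclidean matrices and leaves Euclidean ones alone", {
  # squared EDM of collinear points 0, 1, 2
  edm <- matrix(c(0, 1, 4, 1, 0, 1, 4, 1, 0), 3, 3)
  out <- psd_project(distance_matrix(edm, squared = TRUE))
  expect_equal(out$values, edm, tolerance = 1e-8)

  zero <- matrix(0, 4, 4)
  expect_equal(psd_project(distance_matrix(zero, squared = TRUE))$values, zero)

  # violate the triangle inequality badly
  bad <- matrix(0, 4, 4)
  bad[1, 2] <- bad[2, 1] <- 1
  bad[2, 3] <- bad[3, 2] <- 1
  bad[1, 3] <- bad[3, 1] <- 30
  bad[1, 4] <- bad[4, 1] <- 1
  bad[2, 4] <- bad[4, 2] <- 1
  bad[3, 4] <- bad[4, 3] <- 1
  proj <- psd_project(distance_matrix(bad^2, squared = TRUE))
  n <- 4
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% proj$values %*% J
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  expect_error(distance_matrix(matrix(1:9, 3, 3)), class = "geosec_validation_error")
  diag_bad <- diag(3)
  expect_error(distance_matrix(diag_bad), class = "geosec_validation_error")
})

test_that("PSD projection is idempotent and the identity on valid squared EDMs", {
  set.seed(41)
  for (n in c(4, 6, 9)) {
    edm <- random_sq_edm(n)
    D <- distance_matrix(edm, squared = TRUE)
    p1 <- psd_project(D)
    expect_equal(p1$values, edm, tolerance = 1e-8) # identity on valid EDMs
    noisy <- edm + matrix(runif(n^2, 0, 4), n, n)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    q1 <- psd_project(distance_matrix(noisy, squared = TRUE))
    q2 <- psd_project(q1)
    expect_equal(q2$values, q1$values, tolerance = 1e-8) # idempotent
  }
})

test_that("distance perturbation is seeded and returns Euclidean-consistent quadruples", {
  q <- quad_distances(1, 1, 1, sqrt(2), sqrt(2), 1)
  expect_equal(unclass(perturb_distances(q, 0)), unclass(q), tolerance = 1e-8)
  a <- perturb_distances(q, 0.1, seed = 7)
  b <- perturb_distances(q, 0.1, seed = 7)
  expect_equal(unclass(a), unclass(b))
  # projected output must describe a realizable point set
  m2 <- quad_to_matrix(a)^2
  J <- diag(4) - matrix(1 / 4, 4, 4)
  G <- -0.5 * J %*% m2 %*% J
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # and its dihedral is computable
  expect_true(abs(cos_dihedral_from_distances(a)) <= 1)
})

test_that("cosine perturbation clamps, preserves masks and has the requested spread", {
  x <- c(0.5, -0.2, NA, 1)
  expect_identical(perturb_cos(x, 0), x)
  y <- perturb_cos(x, 0.2, seed = 3)
  expect_true(is.na(y[3]))
  expect_true(all(abs(y[!is.na(y)]) <= 1))
  expect_lte(perturb_cos(1, 0.5, seed = 4), 1)
  draws <- perturb_cos(rep(0, 1e5), 0.05, seed = 5)
  expect_gt(sd(draws), 0.048)
  expect_lt(sd(draws), 0.052)
})

test_that("Monte-Carlo angle error follows the delta-method prediction and grows with noise", {
  expect_equal(
    monte_carlo_omega_error(omega = c(45, 90), eta2 = 0, n_trials = 10, seed = 1)$mean_abs_error,
    c(0, 0)
  )
  sim <- monte_carlo_omega_error(omega = 90, eta2 = 0.05, n_trials = 20000, seed = 2)
  delta <- 0.05 * (180 / pi) * sqrt(2 / pi)
  expect_equal(sim$mean_abs_error, delta, tolerance = 0.1)
  # monotone in eta2 at fixed omega
  sims <- monte_carlo_omega_error(omega = 60, eta2 = c(0.02, 0.05, 0.1), n_trials = 5000, seed = 3)
  expect_true(all(diff(sims$mean_abs_error) > 0))
  expect_warning(monte_carlo_omega_error(omega = 0, eta2 = 0.05, n_trials = 10, seed = 4), "inflates")
  expect_error(monte_carlo_omega_error(omega = 200, eta2 = 0.05), class = "geosec_validation_error")
})

test_that("trihedron-angle noise perturbs the dihedral cosine smoothly", {
  p <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 1, 1, 1), 4, 3, byrow = TRUE)
  tc <- trihedron_cosines(quad_from_coords(p))
  clean <- perturb_trihedron_angles(acos(tc[1]), acos(tc[2]), acos(tc[3]), eta = 0)
  expect_equal(clean, cos_dihedral_from_coords(p[1, ], p[2, ], p[3, ], p[4, ]))
  noisy <- perturb_trihedron_angles(acos(tc[1]), acos(tc[2]), acos(tc[3]), eta = 0.05, seed = 6)
  expect_true(abs(noisy) <= 1)
})

test_that("graph cosine noise respects masks and refreshes node aggregates", {
  b <- build_backbone(dplyr::bind_rows(
    segment_spec("alpha", 6), segment_spec("beta", 5)
  ), seed = 43)
  g <- featurize_structure(b$structure)
  g$edges$phi_ok[1] <- FALSE
  g$edges$cos_phi[1] <- 0
  gn <- perturb_graph_cosines(g, 0.1, seed = 9)
  expect_equal(gn$edges$cos_phi[1], 0) # masked sentinel untouched
  expect_false(isTRUE(all.equal(gn$edges$cos_phi[-1], g$edges$cos_phi[-1])))
  expect_equal(gn$edges$d, g$edges$d) # distances untouched
  expect_false(isTRUE(all.equal(gn$nodes$nf_cos_phi, g$nodes$nf_cos_phi)))
})
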