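# Noise channels and geometric consistency restoration.
#
# Three perturbation channels mirror how measurement imprecision enters the
# featurization: (1) Gaussian noise on inter-atomic distances followed by
# projection of the squared distance matrix onto the cone of Euclidean
# distance matrices (classical double-centering / PSD eigenvalue clipping),
# (2) Gaussian noise on the trihedron face angles, and (3) Gaussian noise
# directly on dihedral cosines, the channel used for the robustness study.
# A Monte-Carlo routine quantifies the angle error that cosine noise
# induces.

#' Symmetric distance matrix container
#'
#' @param values Symmetric non-negative matrix with zero diagonal.
#' @param squared Are the entries squared distances?
#' @return An object of class `dist_matrix`.
#' @export
distance_matrix <- function(values, squared = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_validation("distance matrix must be square")
  if (max(abs(values - t(values))) > 1e-12) stop_validation("distance matrix must be symmetric")
  if (max(abs(diag(values))) > 1e-12) stop_validation("distance matrix must have a zero diagonal")
  structure(list(values = values, squared = isTRUE(squared)), class = "dist_matrix")
}

#' Project a distance matrix onto the Euclidean (PSD Gram) cone
#'
#' Restores geometric consistency of a noisy distance matrix: the squared
#' matrix is double-centered (`G = -1/2 J D J`, `J = I - 11'/n`), negative
#' eigenvalues of the Gram matrix are clipped to zero, and the projected
#' squared distances are rebuilt as `E_ii + E_jj - 2 E_ij`. The output's
#' double-centered Gram is positive semidefinite, so the distances describe
#' a realizable Euclidean point set. Valid squared Euclidean distance
#' matrices are fixed points; the operator is idempotent.
#'
#' Plain (unsquared) inputs are squared internally and un-squared on output.
#'
#' @param D A [distance_matrix()].
#' @return A [distance_matrix()] with the same `squared` flag.
#' @export
psd_project <- function(D) {
  stopifnot(inherits(D, "dist_matrix"))
  V <- D$values
  D2 <- if (D$squared) V else V^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  E <- eg$vectors %*% (lam * t(eg$vectors))
  dE <- diag(E)
  P2 <- outer(dE, dE, "+") - 2 * E
  P2 <- pmax((P2 + t(P2)) / 2, 0)
  diag(P2) <- 0
  distance_matrix(if (D$squared) P2 else sqrt(P2), squared = D$squared)
}

#' Perturb a quadruple's distances with Gaussian noise, then re-project
#'
#' Adds i.i.d. `N(0, eta1)` noise to the off-diagonal entries of the 4 x 4
#' distance matrix (symmetrically, zero diagonal), projects the squared
#' matrix back onto the Euclidean cone, and returns the six projected
#' distances.
#'
#' @param q A [quad_distances()] object.
#' @param eta1 Noise standard deviation in Angstrom (>= 0).
#' @param seed Optional integer seed (reproducible draws).
#' @return A [quad_distances()] object.
#' @export
perturb_distances <- function(q, eta1, seed = NULL) {
  if (!is_number(eta1) || eta1 < 0) stop_validation("`eta1` must be >= 0")
  m <- quad_to_matrix(q)
  eps <- with_seed(seed, rnorm(6, 0, eta1))
  noisy <- m
  noisy[upper.tri(noisy)] <- noisy[upper.tri(noisy)] + eps
  noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
  proj <- psd_project(distance_matrix(noisy^2, squared = TRUE))
  quad_from_matrix(sqrt(proj$values))
}

#' Perturb cosine values with Gaussian noise
#'
#' Adds i.i.d. `N(0, eta2)` noise and clamps to `[-1, 1]`. `NA` entries
#' (masked features) pass through untouched.
#'
#' @param x Numeric vector of cosines in `[-1, 1]` (may contain `NA`).
#' @param eta2 Noise standard deviation (>= 0, dimensionless).
#' @param seed Optional integer seed.
#' @return Perturbed cosines, same length and `NA` pattern as `x`.
#' @export
perturb_cos <- function(x, eta2, seed = NULL) {
  if (!is_number(eta2) || eta2 < 0) stop_validation("`eta2` must be >= 0")
  if (eta2 == 0) return(x)
  eps <- with_seed(seed, rnorm(length(x), 0, eta2))
  out <- clamp(x + eps)
  out[is.na(x)] <- NA_real_
  out
}

#' Dihedral cosine from noisy trihedron face angles
#'
#' The alternative noise channel: perturbs the three face angles (radians)
#' with i.i.d. `N(0, eta)` and recomputes `cos(omega)` through the trihedron
#' cosine law. Not used in the main pipeline (cosine noise is), provided for
#' comparison of the two channels.
#'
#' @param alpha,beta,gamma Face angles in radians.
#' @param eta Angle noise standard deviation in radians (>= 0).
#' @param seed Optional integer seed.
#' @return Perturbed `cos(omega)`.
#' @export
perturb_trihedron_angles <- function(alpha, beta, gamma, eta, seed = NULL) {
  if (!is_number(eta) || eta < 0) stop_validation("`eta` must be >= 0")
  eps <- with_seed(seed, rnorm(3, 0, eta))
  cos_dihedral_from_trihedron(
    cos(alpha + eps[1]), cos(beta + eps[2]), cos(gamma + eps[3])
  )
}

#' Monte-Carlo estimate of the angle error induced by cosine noise
#'
#' For every combination of `omega` (degrees) and noise level `eta2`, draws
#' `n_trials` perturbations `clamp(cos(omega) + N(0, eta2))`, maps them back
#' through `acos`, and summarises the angular error. The mean absolute
#' error is the primary estimator; the root-mean-square error is reported
#' alongside.
#'
#' @param omega Dihedral angles in degrees, inside `(0, 180)`; the exact
#'   endpoints are accepted with a warning (the error estimate inflates
#'   there because `acos` folds the noise one-sidedly).
#' @param eta2 One or more cosine noise levels (std, >= 0).
#' @param n_trials Trials per condition (>= 1).
#' @param seed Optional integer seed.
#' @return Tibble with columns `omega`, `eta2`, `mean_abs_error`,
#'   `rms_error` (degrees).
#' @export
monte_carlo_omega_error <- function(omega = seq(30, 150, by = 30),
                                    eta2 = c(0.05, 0.1),
                                    n_trials = 1000, seed = NULL) {
  if (any(!is.finite(omega)) || any(omega < 0 | omega > 180)) {
    stop_validation("`omega` values must lie in [0, 180] degrees")
  }
  if (any(omega %in% c(0, 180))) {
    warn("omega at 0 or 180 degrees: acos folds the noise one-sidedly and the error estimate inflates")
  }
  if (any(eta2 < 0)) stop_validation("`eta2` must be >= 0")
  if (!is_count(n_trials, min = 1)) stop_validation("`n_trials` must be a positive integer")
  grid <- tidyr::expand_grid(omega = omega, eta2 = eta2)
  with_seed(seed, {
    res <- purrr::pmap_dfr(grid, function(omega, eta2) {
      err <- rad2deg(acos(clamp(cos(deg2rad(omega)) + rnorm(n_trials, 0, eta2)))) - omega
      tibble::tibble(
        mean_abs_error = mean(abs(err)),
        rms_error = sqrt(mean(err^2))
      )
    })
    dplyr::bind_cols(grid, res)
  })
}

#' Add cosine noise to the angle features of a featurized graph
#'
#' Applies [perturb_cos()] to every cosine channel of the edge features
#' (masked entries untouched) and refreshes aggregated node features when
#' present, so the graph can be fed to a classifier as a noisy input.
#'
#' @param g A `residue_graph` with features attached.
#' @param eta2 Cosine noise level (std).
#' @param seed Optional integer seed.
#' @return The perturbed `residue_graph`.
#' @export
perturb_graph_cosines <- function(g, eta2, seed = NULL) {
  if (!isTRUE(g$meta$features_attached)) stop_validation("attach_edge_features() first")
  cos_channels <- setdiff(g$meta$feature_channels, "d")
  with_seed(seed, {
    for (ch in cos_channels) {
      ok <- g$edges[[paste0(sub("^cos_", "", ch), "_ok")]]
      vals <- g$edges[[ch]]
      vals[!ok] <- NA_real_
      vals <- perturb_cos(vals, eta2)
      vals[!ok] <- 0
      g$edges[[ch]] <- vals
    }
    NULL
  })
  if (any(grepl("^nf_", names(g$nodes)))) {
    g <- aggregate_node_features(g, include_res_type = isTRUE(g$meta$include_res_type))
  }
  g
}
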