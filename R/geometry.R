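# Distance-only dihedral geometry.
#
# A dihedral angle omega over an ordered atom quadruple (i-3, i-2, i-1, i)
# can be recovered, up to sign, from the six pairwise distances alone: the
# three planar angles alpha, beta, gamma at the vertex i-2 obey the trihedron
# cosine law
#
#     cos(gamma) = cos(alpha) cos(beta) + sin(alpha) sin(beta) cos(omega)
#
# so cos(omega) follows from the law of cosines applied to three triangles.
# Only the cosine is recoverable (distances are mirror-invariant), which is
# why every downstream feature in this package is a cosine.

#' Six pairwise distances of an ordered atom quadruple
#'
#' Container for the distances among four ordered atoms, indexed 0..3 where
#' index 0 plays the role of atom i-3 and index 3 the role of atom i. Field
#' `dab` is the distance between atoms `a` and `b` in Angstrom.
#'
#' @param d01,d12,d23 Distances between consecutive atoms (Angstrom).
#' @param d02,d13 Second-neighbour distances.
#' @param d03 End-to-end distance.
#' @return An object of class `quad_distances` (named numeric vector).
#' @examples
#' quad_distances(1, 1, 1, sqrt(2), sqrt(2), 1) # planar unit square
#' @export
quad_distances <- function(d01, d12, d23, d02, d13, d03) {
  q <- c(d01 = d01, d12 = d12, d23 = d23, d02 = d02, d13 = d13, d03 = d03)
  if (!all(is.finite(q)) || any(q <= 0)) {
    stop_validation("all six quadruple distances must be finite and strictly positive")
  }
  structure(q, class = "quad_distances")
}

#' Pairwise distances of four points as a `quad_distances` object
#'
#' @param p A 4 x 3 matrix of coordinates, rows ordered as atoms (i-3 .. i).
#' @return A [quad_distances()] object.
#' @export
quad_from_coords <- function(p) {
  p <- as.matrix(p)
  if (!all(dim(p) == c(4, 3))) stop_validation("`p` must be a 4 x 3 coordinate matrix")
  d <- as.matrix(stats::dist(p))
  quad_distances(d[1, 2], d[2, 3], d[3, 4], d[1, 3], d[2, 4], d[1, 4])
}

#' Convert a quadruple to / from its 4 x 4 distance matrix
#'
#' @param q A [quad_distances()] object.
#' @return `quad_to_matrix()`: a symmetric 4 x 4 matrix with zero diagonal;
#'   `quad_from_matrix()`: a [quad_distances()] object.
#' @export
quad_to_matrix <- function(q) {
  stopifnot(inherits(q, "quad_distances"))
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- q[["d01"]]
  m[2, 3] <- m[3, 2] <- q[["d12"]]
  m[3, 4] <- m[4, 3] <- q[["d23"]]
  m[1, 3] <- m[3, 1] <- q[["d02"]]
  m[2, 4] <- m[4, 2] <- q[["d13"]]
  m[1, 4] <- m[4, 1] <- q[["d03"]]
  m
}

#' @rdname quad_to_matrix
#' @param m A symmetric 4 x 4 distance matrix.
#' @export
quad_from_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4, 4))) stop_validation("`m` must be 4 x 4")
  quad_distances(m[1, 2], m[2, 3], m[3, 4], m[1, 3], m[2, 4], m[1, 4])
}

#' Planar angle cosine from three side lengths (law of cosines)
#'
#' Returns `(x^2 + y^2 - z^2) / (2 x y)`, the cosine of the angle between two
#' triangle sides of lengths `x` and `y` whose opposite side has length `z`.
#' No clamping is applied: callers validate the result.
#'
#' @param x,y Adjacent side lengths (must be positive).
#' @param z Opposite side length.
#' @return The cosine (may fall outside `[-1, 1]` for non-metric inputs).
#' @examples
#' planar_cos(1, 1, 1) # 0.5, equilateral
#' planar_cos(3, 4, 5) # 0, right angle
#' @export
planar_cos <- function(x, y, z) {
  if (any(x <= 0) || any(y <= 0)) {
    stop_degenerate("planar_cos requires strictly positive adjacent side lengths")
  }
  (x^2 + y^2 - z^2) / (2 * x * y)
}

#' Trihedron face-angle cosines of an atom quadruple
#'
#' The three planar angles at vertex i-2: alpha between (i-3, i-1),
#' beta between (i-1, i) and gamma between (i-3, i), each computed from
#' distances with the law of cosines.
#'
#' @param q A [quad_distances()] object.
#' @return Named numeric vector `(cos_alpha, cos_beta, cos_gamma)`.
#' @export
trihedron_cosines <- function(q) {
  stopifnot(inherits(q, "quad_distances"))
  c(
    cos_alpha = planar_cos(q[["d12"]], q[["d01"]], q[["d02"]]),
    cos_beta  = planar_cos(q[["d12"]], q[["d13"]], q[["d23"]]),
    cos_gamma = planar_cos(q[["d01"]], q[["d13"]], q[["d03"]])
  )
}

#' Dihedral cosine from trihedron face-angle cosines
#'
#' Inverts the trihedron cosine law:
#' `cos(omega) = (cos(gamma) - cos(alpha) cos(beta)) / (sin(alpha) sin(beta))`.
#'
#' @param cos_alpha,cos_beta,cos_gamma Face-angle cosines, each in `[-1, 1]`
#'   with `cos_alpha`, `cos_beta` strictly inside.
#' @param tol Boundary tolerance for the final clamp.
#' @return `cos(omega)` in `[-1, 1]`.
#' @export
cos_dihedral_from_trihedron <- function(cos_alpha, cos_beta, cos_gamma, tol = 1e-9) {
  clamp_cosine(c(cos_alpha, cos_beta), tol = tol)
  if (any(abs(c(cos_alpha, cos_beta)) >= 1 - tol)) {
    stop_degenerate("collinear atom triple: sin(alpha) or sin(beta) vanishes")
  }
  num <- cos_gamma - cos_alpha * cos_beta
  den <- sqrt(1 - cos_alpha^2) * sqrt(1 - cos_beta^2)
  clamp_cosine(num / den, tol = tol)
}

#' Dihedral cosine from distances only
#'
#' Computes `cos(omega)` for the dihedral between the planes (i-3, i-2, i-1)
#' and (i-2, i-1, i) using nothing but the six pairwise distances of the
#' quadruple. The result is clamped to `[-1, 1]` only when within `tol` of
#' the boundary; larger violations raise a geometry-inconsistency error
#' (the distances then do not describe a Euclidean point set).
#'
#' @param q A [quad_distances()] object.
#' @param tol Boundary tolerance (default `1e-9`).
#' @return `cos(omega)` in `[-1, 1]`.
#' @examples
#' # planar unit square: cis, omega = 0
#' cos_dihedral_from_distances(quad_distances(1, 1, 1, sqrt(2), sqrt(2), 1))
#' # planar zigzag: trans, omega = pi
#' cos_dihedral_from_distances(quad_distances(1, 1, 1, sqrt(2), sqrt(2), sqrt(5)))
#' @export
cos_dihedral_from_distances <- function(q, tol = 1e-9) {
  tc <- trihedron_cosines(q)
  cos_dihedral_from_trihedron(tc[["cos_alpha"]], tc[["cos_beta"]], tc[["cos_gamma"]],
    tol = tol
  )
}

#' Dihedral cosine from Cartesian coordinates
#'
#' Coordinate-based reference: the cosine of the angle between the plane
#' normals `b1 x b2` and `b2 x b3`, where `b_k` are the successive bond
#' vectors of the quadruple. A cis (omega = 0) configuration gives +1 and a
#' trans (omega = pi) configuration gives -1.
#'
#' @param p0,p1,p2,p3 Numeric 3-vectors (Angstrom).
#' @return `cos(omega)` in `[-1, 1]`.
#' @export
cos_dihedral_from_coords <- function(p0, p1, p2, p3) {
  b1 <- p1 - p0
  b2 <- p2 - p1
  b3 <- p3 - p2
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  l1 <- sqrt(sum(n1^2))
  l2 <- sqrt(sum(n2^2))
  if (l1 < 1e-12 || l2 < 1e-12) {
    stop_degenerate("collinear atom triple: dihedral plane is undefined")
  }
  clamp(sum(n1 * n2) / (l1 * l2))
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Safe variant: masked features (NA) instead of aborts, so partial
# structures survive featurization.
cos_dihedral_or_na <- function(p0, p1, p2, p3) {
  tryCatch(
    cos_dihedral_from_coords(p0, p1, p2, p3),
    geosec_degenerate_geometry = function(e) NA_real_
  )
}

#' Generalized phi/psi cosines for a residue pair
#'
#' Extends the classical backbone dihedrals to any spatially close residue
#' pair (k, l), connected or not along the primary sequence:
#' * `cos_phi`: dihedral over (C of k, N of l, CA of l, C of l);
#' * `cos_psi`: dihedral over (N of k, CA of k, C of k, N of l).
#'
#' When k and l are sequence-adjacent this reduces exactly to the classical
#' phi of l and psi of k. Missing atoms or degenerate geometry yield `NA`
#' (a masked feature), not an error, so that partial structures can still be
#' featurized.
#'
#' @param s A [protein_structure()] in all-backbone mode.
#' @param k,l Residue indices (`res_id`, 1-based position in the residue list).
#' @return Named numeric vector `(cos_phi, cos_psi)`; entries are `NA` when
#'   the needed atoms are absent or collinear.
#' @export
generalized_phi_psi <- function(s, k, l) {
  coords <- residue_coords(s)
  if (k == l) stop_degenerate("generalized phi/psi is undefined for a residue paired with itself")
  if (k < 1 || l < 1 || k > length(coords) || l > length(coords)) {
    stop_validation("residue index out of range")
  }
  rk <- coords[[k]]
  rl <- coords[[l]]
  phi <- if (all(c("C") %in% rownames(rk)) && all(c("N", "CA", "C") %in% rownames(rl))) {
    cos_dihedral_or_na(rk["C", ], rl["N", ], rl["CA", ], rl["C", ])
  } else {
    NA_real_
  }
  psi <- if (all(c("N", "CA", "C") %in% rownames(rk)) && "N" %in% rownames(rl)) {
    cos_dihedral_or_na(rk["N", ], rk["CA", ], rk["C", ], rl["N", ])
  } else {
    NA_real_
  }
  c(cos_phi = phi, cos_psi = psi)
}

#' C-alpha pseudo-dihedral cosine for a residue pair
#'
#' On a C-alpha-only trace the quadruple is anchored on the pair itself:
#' atom i-1 is CA of residue `a`, atom i-2 is CA of residue `b`; atom i is
#' the CA spatially nearest to CA(a) among all other CAs (excluding CA(a)
#' and CA(b)), and atom i-3 the CA nearest to CA(b) (excluding CA(a), CA(b)
#' and the atom already chosen as i). Distance ties are broken by the lower
#' residue list index, deterministically.
#'
#' @param s A [protein_structure()] with at least 4 residues carrying CA atoms.
#' @param a,b Residue indices (`res_id`).
#' @return `cos` of the pseudo-dihedral, or `NA` when the anchors are
#'   collinear (masked feature).
#' @export
ca_pseudo_dihedral <- function(s, a, b) {
  ca <- ca_matrix(s)
  n <- nrow(ca)
  if (n < 4) stop_insufficient("C-alpha pseudo-dihedral needs at least 4 residues with CA atoms")
  if (a == b) stop_degenerate("pseudo-dihedral is undefined for a residue paired with itself")
  if (anyNA(ca[c(a, b), ])) return(NA_real_)
  i_near <- nearest_ca(ca, ref = a, exclude = c(a, b))
  i3_near <- nearest_ca(ca, ref = b, exclude = c(a, b, i_near))
  if (is.na(i_near) || is.na(i3_near)) return(NA_real_)
  cos_dihedral_or_na(ca[i3_near, ], ca[b, ], ca[a, ], ca[i_near, ])
}

# Index of the CA nearest to row `ref`, excluding `exclude`; ties broken by
# the lowest residue index. NA coordinates never win.
nearest_ca <- function(ca, ref, exclude) {
  d2 <- rowSums((ca - matrix(ca[ref, ], nrow(ca), 3, byrow = TRUE))^2)
  d2[exclude] <- Inf
  d2[!is.finite(d2)] <- Inf
  if (all(is.infinite(d2))) return(NA_integer_)
  which.min(d2) # first minimum = lowest index on ties
}
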