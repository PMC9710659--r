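# Independent oracles and shared fixtures.

# Coordinate-based dihedral cosine, written against pracma's cross product
# and kept independent of the package's own geometry code.
oracle_dihedral_cos <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
}

# Random non-degenerate 4-point configuration (rejects near-collinear
# triples so both routes are well-defined).
random_quadruple <- function() {
  repeat {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    b1 <- p[2, ] - p[1, ]
    b2 <- p[3, ] - p[2, ]
    b3 <- p[4, ] - p[3, ]
    s1 <- sqrt(sum(pracma::cross(b1, b2)^2))
    s2 <- sqrt(sum(pracma::cross(b2, b3)^2))
    if (s1 > 0.1 && s2 > 0.1 && min(dist(p)) > 0.1) {
      return(p)
    }
  }
}

# Squared Euclidean distance matrix of a random 3-D point set.
random_sq_edm <- function(n) {
  pts <- matrix(rnorm(n * 3), n, 3)
  unname(as.matrix(dist(pts))^2)
}

# Small featurized synthetic dataset shared by classifier tests.
tiny_dataset <- function(n_proteins = 6, jitter = 5, seed = 42, mode = "backbone") {
  ds <- generate_dataset(
    n_proteins = n_proteins, length_range = c(20, 30),
    jitter = jitter, seed = seed
  )
  lapply(ds, function(e) {
    s <- if (mode == "ca") {
      as_protein_structure(tibble::as_tibble(e$structure), mode = "ca", source = "synthetic")
    } else {
      e$structure
    }
    list(structure = s, graph = featurize_structure(s), labels = e$labels)
  })
}
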