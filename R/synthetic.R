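# Synthetic labelled backbones.
#
# Chains are grown by sequential internal-coordinate (NeRF) placement with
# ideal bond geometry (N-CA 1.46 A, CA-C 1.52 A, C-N 1.33 A; bond angles
# N-CA-C 111.0, CA-C-N 116.2, C-N-CA 121.7 degrees; peptide omega fixed at
# 180 degrees) and per-segment dihedrals: alpha -57/-47, beta -139/+135,
# coil drawn per residue from a polyproline-II-adjacent basin
# (phi ~ U(-100,-75), psi ~ U(-20,30)). The coil basin deliberately avoids
# the alpha and beta basins *in cosine space*: featurization only ever sees
# cosines, and cosine is even, so e.g. phi = +57 would alias onto the helix
# basin. Carbonyl O atoms are placed in the peptide plane opposite the next
# amide nitrogen.

IDEAL_GEOM <- list(
  b_n_ca = 1.46, b_ca_c = 1.52, b_c_n = 1.33, b_c_o = 1.23,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  omega = 180
)

#' Specify a secondary-structure segment for the synthetic generator
#'
#' @param ss_class `"alpha"`, `"beta"` or `"coil"`.
#' @param length Number of residues (>= 1).
#' @param phi,psi Segment dihedrals in degrees. Defaults: alpha -57/-47,
#'   beta -139/+135; coil ignores them and samples per residue.
#' @param jitter Standard deviation (degrees) of Gaussian dihedral noise.
#' @return One-row tibble describing the segment.
#' @export
segment_spec <- function(ss_class = c("alpha", "beta", "coil"), length = 8,
                         phi = NULL, psi = NULL, jitter = 0) {
  ss_class <- match.arg(ss_class)
  if (!is_count(length, min = 1)) stop_validation("`length` must be a positive integer")
  if (!is_number(jitter) || jitter < 0) stop_validation("`jitter` must be >= 0")
  defaults <- switch(ss_class,
    alpha = c(-57, -47), beta = c(-139, 135), coil = c(NA_real_, NA_real_)
  )
  tibble::tibble(
    ss_class = ss_class, length = as.integer(length),
    phi = phi %||% defaults[1], psi = psi %||% defaults[2], jitter = jitter
  )
}

# NeRF: place atom d bonded to c with |cd| = bond, angle(b,c,d) = angle_deg
# and torsion(a,b,c,d) = torsion_deg.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Per-residue (phi, psi, letter) draws for a segment table.
draw_dihedrals <- function(segments) {
  purrr::pmap_dfr(segments, function(ss_class, length, phi, psi, jitter) {
    if (ss_class == "coil") {
      phi_i <- runif(length, -100, -75)
      psi_i <- runif(length, -20, 30)
    } else {
      phi_i <- rep(phi, length)
      psi_i <- rep(psi, length)
    }
    if (jitter > 0) {
      phi_i <- phi_i + rnorm(length, 0, jitter)
      psi_i <- psi_i + rnorm(length, 0, jitter)
    }
    letter <- switch(ss_class, alpha = "H", beta = "E", coil = "-")
    tibble::tibble(phi = phi_i, psi = psi_i, letter = letter)
  })
}

#' Build a labelled synthetic backbone from segment specifications
#'
#' @param segments Tibble of segments (rows from [segment_spec()], e.g.
#'   `dplyr::bind_rows(segment_spec("alpha", 10), segment_spec("coil", 4))`).
#' @param seed Optional integer; when given, the build is reproducible and
#'   the caller's RNG state is untouched.
#' @param scheme Labelling scheme of the returned labels.
#' @param chain Chain identifier written into the structure.
#' @return List with `structure` (a `protein_structure`, backbone mode) and
#'   `labels` (an `ss_labels` tibble aligned to `res_id`, including the
#'   8-state `letter` column).
#' @export
build_backbone <- function(segments, seed = NULL, scheme = "alpha-beta-other", chain = "A") {
  if (nrow(segments) < 1) stop_validation("at least one segment is required")
  with_seed(seed, {
    dih <- draw_dihedrals(segments)
    n <- nrow(dih)
    g <- IDEAL_GEOM
    N <- matrix(NA_real_, n, 3)
    CA <- matrix(NA_real_, n, 3)
    C <- matrix(NA_real_, n, 3)
    O <- matrix(NA_real_, n, 3)
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(g$b_n_ca, 0, 0)
    ang <- deg2rad(g$a_n_ca_c)
    C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
    for (i in seq_len(n)) {
      if (i < n) {
        N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, dih$psi[i])
        CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca, g$a_c_n_ca, g$omega)
        C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c, g$a_n_ca_c, dih$phi[i + 1])
      }
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, dih$psi[i] + 180)
    }
    res_type <- sample(AA3, n, replace = TRUE)
    per_atom <- function(m, nm) {
      tibble::tibble(
        chain = chain, resnum = seq_len(n), res_type = res_type,
        atom = nm, x = m[, 1], y = m[, 2], z = m[, 3]
      )
    }
    atoms <- dplyr::bind_rows(
      per_atom(N, "N"), per_atom(CA, "CA"), per_atom(C, "C"), per_atom(O, "O")
    ) |>
      dplyr::arrange(.data$resnum, match(.data$atom, BACKBONE_ATOMS))
    s <- as_protein_structure(atoms, mode = "backbone", source = "synthetic")
    labels <- map_labels(
      tibble::tibble(
        res_id = seq_len(n), chain = chain, resnum = seq_len(n), letter = dih$letter
      ),
      scheme = scheme
    )
    list(structure = s, labels = labels)
  })
}

#' Generate a reproducible dataset of labelled synthetic proteins
#'
#' Each protein is a random concatenation of alpha, beta and coil segments
#' (segment classes drawn from `class_mix`; lengths 6-14 for alpha, 4-10 for
#' beta, 3-8 for coil), trimmed to a total length drawn from `length_range`.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param length_range Integer range of total residue counts.
#' @param class_mix Named weights for `alpha`, `beta`, `coil` segment draws.
#' @param jitter Dihedral noise (degrees std) applied to every residue.
#' @param seed Integer seed; the dataset is identical across calls with the
#'   same arguments.
#' @param scheme Labelling scheme of the returned labels.
#' @return List of `list(structure =, labels =)` entries.
#' @export
generate_dataset <- function(n_proteins = 60, length_range = c(45, 75),
                             class_mix = c(alpha = 0.4, beta = 0.3, coil = 0.3),
                             jitter = 5, seed = 1, scheme = "alpha-beta-other") {
  if (!is_count(n_proteins, min = 2)) stop_validation("`n_proteins` must be an integer >= 2")
  mix <- class_mix[c("alpha", "beta", "coil")]
  if (anyNA(mix) || any(mix < 0) || sum(mix) <= 0) {
    stop_validation("`class_mix` must contain non-negative alpha/beta/coil weights")
  }
  seg_len <- list(alpha = 6:14, beta = 4:10, coil = 3:8)
  with_seed(seed, {
    lapply(seq_len(n_proteins), function(i) {
      target <- sample(seq.int(length_range[1], length_range[2]), 1)
      segs <- list()
      total <- 0L
      while (total < target) {
        cls <- sample(names(mix), 1, prob = mix)
        len <- sample(seg_len[[cls]], 1)
        len <- min(len, target - total + 0L)
        if (len >= 1) segs[[length(segs) + 1]] <- segment_spec(cls, len, jitter = jitter)
        total <- total + len
      }
      build_backbone(dplyr::bind_rows(segs), scheme = scheme)
    })
  })
}

#' Write a structure as a minimal PDB file
#'
#' Emits standard fixed-width ATOM records (plus END) readable by
#' [read_structure()] and by conventional structure software. Coordinates
#' are written at PDB precision (1e-3 A).
#'
#' @param s A `protein_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(s, path) {
  if (!inherits(s, "protein_structure") || nrow(s) == 0) {
    stop_validation("`s` must be a non-empty protein_structure")
  }
  name4 <- ifelse(nchar(s$atom) < 4, sprintf(" %-3s", s$atom), s$atom)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(s)), name4, s$res_type, substr(s$chain, 1, 1), s$resnum,
    substr(paste0(s$icode, " "), 1, 1), s$x, s$y, s$z, 1, 0,
    toupper(substr(s$element, 1, 2))
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
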