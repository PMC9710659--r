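# Sequence-agnostic residue graphs.
#
# Nodes are residues; edges connect spatially close residues regardless of
# their position in (or absence from) the primary sequence. Two standard
# constructions are provided: a k-nearest-neighbour graph symmetrized by
# union (method A, default k = 2) and a distance-threshold graph (method B,
# default tau = 3 A, strict "<"). Residue-residue distance is the minimum
# over their retained atom pairs (which collapses to the CA-CA distance on
# a C-alpha trace).
#
# Edges are stored directed, both orientations of every undirected edge,
# because the generalized phi/psi features are direction-dependent: the row
# (from = w, to = v) carries the features oriented toward the receiving
# node v, and message passing consumes exactly that row. Unavailable angle
# features are masked (sentinel value 0 plus a FALSE mask bit), never fatal,
# so partial structures survive featurization.

new_residue_graph <- function(nodes, edges, meta) {
  structure(list(nodes = nodes, edges = edges, meta = meta), class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf(
    "# residue_graph: %d nodes, %d undirected edges (method %s, mode %s)%s\n",
    nrow(x$nodes), nrow(x$edges) / 2, x$meta$method, x$meta$mode,
    if (isTRUE(x$meta$features_attached)) ", features attached" else ""
  ))
  invisible(x)
}

# Full matrix of pairwise residue distances (min over atom pairs).
residue_distance_matrix <- function(s) {
  xyz <- cbind(s$x, s$y, s$z)
  ad <- as.matrix(stats::dist(xyz))
  n <- n_residues(s)
  ids <- s$res_id
  D <- matrix(Inf, n, n)
  # min-reduce atom-pair distances into residue pairs (ids are 1..n, so
  # tapply's level order matches residue order)
  grp <- split(seq_len(nrow(s)), ids)
  for (i in seq_len(n)) {
    block <- ad[grp[[i]], , drop = FALSE]
    D[i, ] <- tapply(apply(block, 2, min), ids, min)
  }
  diag(D) <- 0
  D
}

#' Distance between two residues
#'
#' The minimum distance over the retained atoms of the two residues
#' (all-atom backbone mode), or the CA-CA distance in `"ca"` mode.
#'
#' @param s A `protein_structure`.
#' @param i,j Residue indices (`res_id`).
#' @return Distance in Angstrom.
#' @export
residue_distance <- function(s, i, j) {
  n <- n_residues(s)
  if (i < 1 || j < 1 || i > n || j > n) stop_validation("residue index out of range")
  a <- as.matrix(s[s$res_id == i, c("x", "y", "z")])
  b <- as.matrix(s[s$res_id == j, c("x", "y", "z")])
  if (nrow(a) == 0 || nrow(b) == 0) stop_validation("residue without atoms in this mode")
  min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)))
}

graph_nodes <- function(s) {
  rt <- residue_table(s)
  rt[c("res_id", "chain", "resnum", "res_type", "complete_backbone")]
}

directed_edges <- function(pairs) {
  # pairs: 2-column matrix of undirected pairs (i < j); emit both directions
  tibble::tibble(
    from = c(pairs[, 1], pairs[, 2]),
    to = c(pairs[, 2], pairs[, 1])
  )
}

#' Build a k-nearest-neighbour residue graph (method A)
#'
#' Each residue selects its `k` nearest residues by minimum inter-atomic
#' distance; the directed relation is then symmetrized by union (an edge
#' exists if either endpoint selects the other). Distance ties are broken by
#' the lower residue index. `k` larger than `n - 1` is clamped with a
#' warning.
#'
#' @param s A `protein_structure` with at least 2 residues.
#' @param k Number of neighbours (>= 1; default 2).
#' @return A `residue_graph` (features not yet attached; see
#'   [attach_edge_features()]).
#' @export
build_knn_graph <- function(s, k = 2) {
  n <- n_residues(s)
  if (n < 2) stop_insufficient("k-NN graph needs at least 2 residues")
  if (!is_count(k, min = 1)) stop_validation("`k` must be a positive integer")
  if (k > n - 1) {
    warn(sprintf("k = %d clamped to n - 1 = %d", k, n - 1))
    k <- n - 1
  }
  D <- residue_distance_matrix(s)
  sel <- lapply(seq_len(n), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    head(order(d), k) # order() breaks ties by index
  })
  pairs <- unique(do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(pmin(i, sel[[i]]), pmax(i, sel[[i]]))
  })))
  new_residue_graph(
    nodes = graph_nodes(s),
    edges = dplyr::arrange(
      dplyr::mutate(directed_edges(pairs), d = D[cbind(.data$from, .data$to)]),
      .data$from, .data$to
    ),
    meta = list(method = "knn", k = k, tau = NULL, mode = structure_mode(s), features_attached = FALSE)
  )
}

#' Build a distance-threshold residue graph (method B)
#'
#' Undirected edge between residues whose minimum inter-atomic distance is
#' strictly lower than `tau`. Isolated nodes are allowed.
#'
#' @param s A `protein_structure`.
#' @param tau Distance threshold in Angstrom (> 0; default 3).
#' @return A `residue_graph`.
#' @export
build_threshold_graph <- function(s, tau = 3) {
  if (!is_number(tau) || tau <= 0) stop_validation("`tau` must be a positive number")
  n <- n_residues(s)
  if (n < 2) stop_insufficient("threshold graph needs at least 2 residues")
  D <- residue_distance_matrix(s)
  idx <- which(upper.tri(D) & D < tau, arr.ind = TRUE)
  edges <- if (nrow(idx) == 0) {
    tibble::tibble(from = integer(), to = integer(), d = numeric())
  } else {
    dplyr::arrange(
      dplyr::mutate(directed_edges(idx), d = D[cbind(.data$from, .data$to)]),
      .data$from, .data$to
    )
  }
  new_residue_graph(
    nodes = graph_nodes(s), edges = edges,
    meta = list(method = "threshold", k = NULL, tau = tau, mode = structure_mode(s), features_attached = FALSE)
  )
}

#' Attach distance/dihedral-cosine features to graph edges
#'
#' In backbone mode each directed edge (w -> v) receives
#' `(d, cos_phi, cos_psi)` with the generalized dihedrals oriented toward
#' the receiving node v; in `"ca"` mode it receives `(d, cos_pseudo)` with
#' the C-alpha pseudo-dihedral anchored on the pair. Unavailable angles
#' (missing atoms, degenerate geometry) are stored as 0 with a FALSE mask
#' bit.
#'
#' @param g A `residue_graph` built from `s`.
#' @param s The originating `protein_structure`.
#' @return `g` with feature columns on `$edges`.
#' @export
attach_edge_features <- function(g, s) {
  stopifnot(inherits(g, "residue_graph"))
  e <- g$edges
  mode <- g$meta$mode
  if (mode != structure_mode(s)) stop_validation("graph and structure modes differ")
  if (mode == "backbone") {
    coords <- residue_coords(s)
    m <- nrow(e)
    cphi <- cpsi <- numeric(m)
    phi_ok <- psi_ok <- logical(m)
    for (r in seq_len(m)) {
      w <- coords[[e$from[r]]]
      v <- coords[[e$to[r]]]
      phi <- if ("C" %in% rownames(w) && all(c("N", "CA", "C") %in% rownames(v))) {
        cos_dihedral_or_na(w["C", ], v["N", ], v["CA", ], v["C", ])
      } else {
        NA_real_
      }
      psi <- if (all(c("N", "CA", "C") %in% rownames(w)) && "N" %in% rownames(v)) {
        cos_dihedral_or_na(w["N", ], w["CA", ], w["C", ], v["N", ])
      } else {
        NA_real_
      }
      phi_ok[r] <- !is.na(phi)
      psi_ok[r] <- !is.na(psi)
      cphi[r] <- ifelse(is.na(phi), 0, phi)
      cpsi[r] <- ifelse(is.na(psi), 0, psi)
    }
    e$cos_phi <- cphi
    e$cos_psi <- cpsi
    e$phi_ok <- phi_ok
    e$psi_ok <- psi_ok
  } else {
    m <- nrow(e)
    cps <- numeric(m)
    ok <- logical(m)
    can <- n_residues(s) >= 4
    for (r in seq_len(m)) {
      val <- if (can) ca_pseudo_dihedral(s, a = e$to[r], b = e$from[r]) else NA_real_
      ok[r] <- !is.na(val)
      cps[r] <- ifelse(is.na(val), 0, val)
    }
    e$cos_pseudo <- cps
    e$pseudo_ok <- ok
  }
  g$edges <- e
  g$meta$features_attached <- TRUE
  g$meta$feature_channels <- if (mode == "backbone") {
    c("d", "cos_phi", "cos_psi")
  } else {
    c("d", "cos_pseudo")
  }
  g
}

#' Aggregate incident edge features into node features
#'
#' Each node receives the elementwise mean of the feature vectors of its
#' unmasked incoming directed edges (channel-wise: a masked angle on one
#' edge does not discard that edge's distance). Isolated nodes get a zero
#' vector and a mask flag.
#'
#' @param g A `residue_graph` with features attached.
#' @param include_res_type Record that the node feature matrix should also
#'   carry a 21-way one-hot of the residue type (20 amino acids + UNK);
#'   applied by [node_feature_matrix()].
#' @return `g` with `nf_*` columns and `isolated` on `$nodes`.
#' @export
aggregate_node_features <- function(g, include_res_type = TRUE) {
  stopifnot(inherits(g, "residue_graph"))
  if (!isTRUE(g$meta$features_attached)) stop_validation("attach_edge_features() first")
  e <- g$edges
  n <- nrow(g$nodes)
  masked_mean <- function(value, ok, to) {
    num <- rep(0, n)
    cnt <- rep(0, n)
    if (length(value) > 0) {
      agg <- tapply(value * ok, to, sum)
      num[as.integer(names(agg))] <- agg
      agg2 <- tapply(as.numeric(ok), to, sum)
      cnt[as.integer(names(agg2))] <- agg2
    }
    ifelse(cnt > 0, num / cnt, 0)
  }
  always <- rep(TRUE, nrow(e))
  if (g$meta$mode == "backbone") {
    g$nodes$nf_d <- masked_mean(e$d, always, e$to)
    g$nodes$nf_cos_phi <- masked_mean(e$cos_phi, e$phi_ok, e$to)
    g$nodes$nf_cos_psi <- masked_mean(e$cos_psi, e$psi_ok, e$to)
  } else {
    g$nodes$nf_d <- masked_mean(e$d, always, e$to)
    g$nodes$nf_cos_pseudo <- masked_mean(e$cos_pseudo, e$pseudo_ok, e$to)
  }
  g$nodes$isolated <- !(g$nodes$res_id %in% e$to)
  g$meta$include_res_type <- isTRUE(include_res_type)
  g
}

#' Node feature matrix of a featurized graph
#'
#' Rows are nodes in `res_id` order: the aggregated edge-feature means,
#' optionally concatenated with the 21-way residue-type one-hot (controlled
#' by [aggregate_node_features()]'s `include_res_type`).
#'
#' @param g A `residue_graph` after [aggregate_node_features()].
#' @return Numeric matrix, `n_nodes` x `p`.
#' @export
node_feature_matrix <- function(g) {
  nf_cols <- grep("^nf_", names(g$nodes), value = TRUE)
  if (length(nf_cols) == 0) stop_validation("aggregate_node_features() first")
  X <- as.matrix(g$nodes[nf_cols])
  if (isTRUE(g$meta$include_res_type)) {
    types <- c(AA3, "UNK")
    oh <- matrix(0, nrow(g$nodes), length(types),
      dimnames = list(NULL, paste0("aa_", types))
    )
    oh[cbind(seq_len(nrow(oh)), match(g$nodes$res_type, types))] <- 1
    X <- cbind(X, oh)
  }
  X
}

#' Edge feature matrix (masked entries zeroed) of a featurized graph
#'
#' @param g A `residue_graph` with features attached.
#' @return Numeric matrix, one row per directed edge, columns
#'   `g$meta$feature_channels`.
#' @export
edge_feature_matrix <- function(g) {
  if (!isTRUE(g$meta$features_attached)) stop_validation("attach_edge_features() first")
  as.matrix(g$edges[g$meta$feature_channels])
}

#' Randomly remove a fraction of residues
#'
#' Emulates partially observed structures: a uniform random subset of
#' `ceiling(fraction * n)` residues is removed (reproducibly under `seed`)
#' and residue indices are compacted. Graphs must be rebuilt from the
#' reduced structure.
#'
#' @param s A `protein_structure`.
#' @param fraction Fraction in `[0, 1)` of residues to remove.
#' @param seed Optional integer seed.
#' @return The reduced `protein_structure`; the attribute `"ablation_kept"`
#'   records the original `res_id`s of the surviving residues, in order, so
#'   predictions on the reduced structure can be scored against the
#'   original labels.
#' @export
ablate_residues <- function(s, fraction, seed = NULL) {
  if (!is_number(fraction) || fraction < 0 || fraction >= 1) {
    stop_validation("`fraction` must lie in [0, 1)")
  }
  n <- n_residues(s)
  if (fraction == 0) {
    attr(s, "ablation_kept") <- seq_len(n)
    return(s)
  }
  drop_n <- ceiling(fraction * n)
  drop <- with_seed(seed, sample.int(n, drop_n))
  keep_rows <- !(s$res_id %in% drop)
  out <- s[keep_rows, , drop = FALSE]
  kept <- sort(unique(out$res_id))
  out$res_id <- match(out$res_id, kept)
  out <- new_protein_structure(out, mode = structure_mode(s), source = attr(s, "source"))
  attr(out, "ablation_kept") <- kept
  out
}

#' Build, featurize and aggregate a residue graph in one call
#'
#' Convenience wrapper chaining [build_knn_graph()] (or
#' [build_threshold_graph()]), [attach_edge_features()] and
#' [aggregate_node_features()].
#'
#' @param s A `protein_structure`.
#' @param method `"knn"` (method A) or `"threshold"` (method B).
#' @param k Neighbour count for `"knn"`.
#' @param tau Distance threshold (Angstrom) for `"threshold"`.
#' @param include_res_type Carry the residue-type one-hot in node features?
#' @return A fully featurized `residue_graph`.
#' @export
featurize_structure <- function(s, method = c("knn", "threshold"), k = 2, tau = 3,
                                include_res_type = TRUE) {
  method <- match.arg(method)
  g <- if (method == "knn") build_knn_graph(s, k = k) else build_threshold_graph(s, tau = tau)
  g <- attach_edge_features(g, s)
  aggregate_node_features(g, include_res_type = include_res_type)
}

# Rebuild a graph from a (possibly reduced) structure with the same
# construction settings as `g`.
refeaturize_like <- function(g, s) {
  featurize_structure(
    s,
    method = g$meta$method,
    k = g$meta$k %||% 2, tau = g$meta$tau %||% 3,
    include_res_type = isTRUE(g$meta$include_res_type)
  )
}

#' Jaccard overlap of the undirected edge sets of two graphs
#'
#' @param g1,g2 `residue_graph`s over the same node set.
#' @return Jaccard index in `[0, 1]`.
#' @export
edge_jaccard <- function(g1, g2) {
  und <- function(g) {
    e <- g$edges
    unique(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  a <- und(g1)
  b <- und(g2)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Serialize a featurized graph as an edge-list TSV
#'
#' One row per directed edge: `from`, `to`, the feature channels and their
#' mask bits, suitable for caching or external consumption.
#'
#' @param g A `residue_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
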