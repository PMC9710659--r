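# Edge-conditioned message-passing classifier.
#
# Two message-passing layers operate on the residue graph. At layer t the
# message to node v is
#
#     m_v = sum_{w in N(v)} N_t(e_wv) . h_w
#
# where the filter network N_t (a four-layer perceptron with ReLU
# activations) maps the directed edge feature vector e_wv — oriented toward
# the receiving node v — to a hidden x input matrix (continuous
# kernel-based / edge-conditioned convolution). The vertex update is linear,
# h_v <- Theta_t . h_v + m_v, with a ReLU between the two layers, and the
# readout is a two-layer perceptron composed with a softmax, giving one
# class-probability row per residue. Because messages are neighbourhood
# sums, the output is equivariant under node permutation, and because every
# input is a distance or a dihedral cosine it is invariant under rigid-body
# motion — the two properties that make the classifier sequence-agnostic.
#
# Training is standard back-propagation (hand-derived gradients, full-batch
# Adam) on the cross-entropy, with a protein-level 70/30 train/validation
# split; the state with the best validation macro F1 is kept.

#' Configuration of the message-passing classifier
#'
#' @param scheme Labelling scheme (fixes the output class count).
#' @param mode Graph feature mode: `"backbone"` (3 edge channels) or `"ca"`
#'   (2 channels).
#' @param hidden_dim Width of the hidden node state (default 32).
#' @param edge_mlp_widths Widths of the three hidden layers of the filter
#'   network; its fourth (output) layer has `hidden_dim * input_dim` units.
#' @param readout_hidden Width of the readout perceptron's hidden layer.
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam step size.
#' @param patience Stop early after this many epochs without validation
#'   improvement (`Inf` disables).
#' @param val_fraction Fraction of proteins held out for validation
#'   (default 0.3, i.e. a 70/30 protein-level split).
#' @param class_weights `NULL` (uniform), `"balanced"` (inverse class
#'   frequency) or a numeric vector of per-class weights.
#' @param include_res_type Expect the 21-way residue-type one-hot in the
#'   node features?
#' @param ablation_augment Optional numeric vector of ablation fractions:
#'   each training protein (never a validation protein) additionally
#'   contributes one randomly ablated, re-featurized copy per fraction.
#'   Synthetic chains are geometrically homogeneous, unlike experimental
#'   structures with their chain breaks and unobserved residues; this
#'   augmentation re-introduces that heterogeneity so the classifier learns
#'   gap-spanning edge geometry. Requires dataset entries to carry a
#'   `structure` field.
#' @param seed Integer seed controlling initialisation and the split.
#' @return A `mpn_config` list.
#' @export
mpn_config <- function(scheme = "alpha-beta-other", mode = c("backbone", "ca"),
                       hidden_dim = 32, edge_mlp_widths = c(32, 32, 32),
                       readout_hidden = 32, epochs = 120, learning_rate = 0.01,
                       patience = 25, val_fraction = 0.3, class_weights = NULL,
                       include_res_type = TRUE, ablation_augment = NULL, seed = 1) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme, SCHEMES)
  stopifnot(
    is_count(hidden_dim), length(edge_mlp_widths) == 3, all(edge_mlp_widths >= 1),
    is_count(readout_hidden), is_count(epochs), learning_rate > 0,
    val_fraction > 0, val_fraction < 1
  )
  structure(
    list(
      scheme = scheme, mode = mode, n_classes = n_classes(scheme),
      hidden_dim = as.integer(hidden_dim),
      edge_mlp_widths = as.integer(edge_mlp_widths),
      readout_hidden = as.integer(readout_hidden),
      layers = 2L, epochs = as.integer(epochs), learning_rate = learning_rate,
      patience = patience, val_fraction = val_fraction,
      class_weights = class_weights, include_res_type = isTRUE(include_res_type),
      ablation_augment = ablation_augment, seed = as.integer(seed)
    ),
    class = "mpn_config"
  )
}

relu <- function(x) (x > 0) * x

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- parameter handling -----------------------------------------------------

init_linear <- function(n_in, n_out) {
  list(
    W = matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
    b = rep(0, n_out)
  )
}

init_params <- function(config, node_dim, edge_dim) {
  h <- config$hidden_dim
  w <- config$edge_mlp_widths
  p <- c(node_dim, h) # input dims of the two conv layers
  params <- list()
  for (t in 1:2) {
    params[[paste0("conv", t)]] <- list(
      mlp = list(
        init_linear(edge_dim, w[1]),
        init_linear(w[1], w[2]),
        init_linear(w[2], w[3]),
        init_linear(w[3], h * p[t])
      ),
      theta = matrix(rnorm(h * p[t], 0, sqrt(1 / p[t])), h, p[t])
    )
  }
  params$readout <- list(
    init_linear(h, config$readout_hidden),
    init_linear(config$readout_hidden, config$n_classes)
  )
  params
}

walk_params <- function(a, b, fn) {
  # apply fn(a_leaf, b_leaf) elementwise over two parallel parameter trees
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- walk_params(a[[nm]], b[[nm]], fn)
    out
  } else {
    fn(a, b)
  }
}
map_params <- function(a, fn) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- map_params(a[[nm]], fn)
    out
  } else {
    fn(a)
  }
}

# ---- graph assembly ---------------------------------------------------------

# Stack featurized graphs into one block-diagonal problem.
assemble_block <- function(graphs, labels_list, include_res_type) {
  Xs <- list(); Es <- list(); from <- list(); to <- list(); ys <- list()
  offset <- 0L
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (!any(grepl("^nf_", names(g$nodes)))) {
      g <- aggregate_node_features(g, include_res_type = include_res_type)
    }
    Xs[[i]] <- node_feature_matrix(g)
    Es[[i]] <- edge_feature_matrix(g)
    from[[i]] <- g$edges$from + offset
    to[[i]] <- g$edges$to + offset
    if (!is.null(labels_list)) ys[[i]] <- label_vector(labels_list[[i]])
    offset <- offset + nrow(g$nodes)
  }
  list(
    X = do.call(rbind, Xs), E = do.call(rbind, Es),
    from = unlist(from), to = unlist(to),
    y = if (is.null(labels_list)) NULL else unlist(ys),
    n = offset
  )
}

# Standardize the distance channels (node nf_d and edge d); cosines and
# one-hots are already on a unit scale.
norm_stats <- function(block) {
  list(
    x_mu = mean(block$X[, 1]), x_sd = max(stats::sd(block$X[, 1]), 1e-8),
    e_mu = mean(block$E[, 1]), e_sd = max(stats::sd(block$E[, 1]), 1e-8)
  )
}

apply_norm <- function(block, ns) {
  block$X[, 1] <- (block$X[, 1] - ns$x_mu) / ns$x_sd
  block$E[, 1] <- (block$E[, 1] - ns$e_mu) / ns$e_sd
  block
}

# ---- forward / backward -----------------------------------------------------

mlp_forward <- function(mlp, E) {
  A <- list(); Z <- list(E)
  for (l in seq_along(mlp)) {
    A[[l]] <- sweep(Z[[l]] %*% mlp[[l]]$W, 2, -mlp[[l]]$b)
    Z[[l + 1]] <- if (l < length(mlp)) relu(A[[l]]) else A[[l]]
  }
  list(A = A, Z = Z, out = Z[[length(mlp) + 1]])
}

mlp_backward <- function(mlp, cache, dout) {
  grads <- vector("list", length(mlp))
  d <- dout
  for (l in rev(seq_along(mlp))) {
    if (l < length(mlp)) d <- d * (cache$A[[l]] > 0)
    grads[[l]] <- list(W = crossprod(cache$Z[[l]], d), b = colSums(d))
    if (l > 1) d <- d %*% t(mlp[[l]]$W)
  }
  grads
}

conv_forward <- function(layer, H, block, h) {
  p <- ncol(H)
  mlpc <- mlp_forward(layer$mlp, block$E)
  F <- mlpc$out # m x (h*p), column-major blocks of the h x p filter matrix
  Hfrom <- H[block$from, , drop = FALSE]
  m <- nrow(F)
  msg <- matrix(0, m, h)
  for (i in seq_len(p)) {
    cols <- ((i - 1) * h + 1):(i * h)
    msg <- msg + F[, cols, drop = FALSE] * Hfrom[, i]
  }
  M <- matrix(0, block$n, h)
  if (m > 0) {
    agg <- rowsum(msg, group = block$to)
    M[as.integer(rownames(agg)), ] <- agg
  }
  S <- H %*% t(layer$theta) + M
  list(S = S, F = F, mlp_cache = mlpc, Hfrom = Hfrom, H_in = H)
}

conv_backward <- function(layer, cache, block, dS, h) {
  p <- ncol(cache$H_in)
  m <- nrow(cache$F)
  dtheta <- crossprod(dS, cache$H_in)
  dH_in <- dS %*% layer$theta
  dmsg <- dS[block$to, , drop = FALSE]
  dF <- matrix(0, m, h * p)
  dHfrom <- matrix(0, m, p)
  for (i in seq_len(p)) {
    cols <- ((i - 1) * h + 1):(i * h)
    dF[, cols] <- dmsg * cache$Hfrom[, i]
    dHfrom[, i] <- rowSums(cache$F[, cols, drop = FALSE] * dmsg)
  }
  if (m > 0) {
    agg <- rowsum(dHfrom, group = block$from)
    dH_in[as.integer(rownames(agg)), ] <- dH_in[as.integer(rownames(agg)), ] + agg
  }
  list(
    grads = list(mlp = mlp_backward(layer$mlp, cache$mlp_cache, dF), theta = dtheta),
    dH_in = dH_in
  )
}

mpn_forward_block <- function(params, block, config, keep_cache = FALSE) {
  h <- config$hidden_dim
  c1 <- conv_forward(params$conv1, block$X, block, h)
  H1 <- relu(c1$S)
  c2 <- conv_forward(params$conv2, H1, block, h)
  H2 <- c2$S
  ro <- mlp_forward(params$readout, H2)
  P <- softmax_rows(ro$out)
  out <- list(P = P, logits = ro$out)
  if (keep_cache) out <- c(out, list(c1 = c1, H1 = H1, c2 = c2, H2 = H2, ro = ro))
  out
}

mpn_backward_block <- function(params, block, config, cache, class_w) {
  n <- block$n
  y1 <- block$y + 1L
  wts <- class_w[y1]
  wsum <- sum(wts)
  P <- cache$P
  dlogits <- P * wts
  dlogits[cbind(seq_len(n), y1)] <- dlogits[cbind(seq_len(n), y1)] - wts
  dlogits <- dlogits / wsum
  g_ro <- mlp_backward(params$readout, cache$ro, dlogits)
  d <- dlogits %*% t(params$readout[[2]]$W)
  d <- d * (cache$ro$A[[1]] > 0)
  dH2 <- d %*% t(params$readout[[1]]$W)
  b2 <- conv_backward(params$conv2, cache$c2, block, dH2, config$hidden_dim)
  dH1 <- b2$dH_in * (cache$c1$S > 0)
  b1 <- conv_backward(params$conv1, cache$c1, block, dH1, config$hidden_dim)
  # exact log-softmax cross-entropy (no probability clipping, so the loss
  # stays differentiable wherever the softmax is)
  z <- cache$logits
  zmax <- apply(z, 1, max)
  logp_y <- z[cbind(seq_len(n), y1)] - zmax - log(rowSums(exp(z - zmax)))
  loss <- -sum(wts * logp_y) / wsum
  list(
    grads = list(conv1 = b1$grads, conv2 = b2$grads, readout = g_ro),
    loss = loss
  )
}

# ---- training ---------------------------------------------------------------

#' Train the message-passing classifier
#'
#' Splits the proteins 70/30 into train/validation (seeded, protein-level —
#' residues of one protein never straddle the split), minimises the
#' (optionally class-weighted) cross-entropy with full-batch Adam, and
#' returns the parameters of the epoch with the best validation macro F1.
#'
#' @param dataset List of `list(graph =, labels =)` entries; graphs must
#'   share one feature mode and labels one scheme. Graphs may be featurized
#'   ([attach_edge_features()]) with or without aggregated node features.
#' @param config An [mpn_config()].
#' @param verbose Print a progress line every 10 epochs?
#' @return An object of class `mpn_model` (parameters, config, training
#'   history). [tidy()] returns the history, [glance()] a one-row summary.
#' @export
train_model <- function(dataset, config = mpn_config(), verbose = FALSE) {
  if (length(dataset) < 2) {
    stop_validation("training needs at least 2 proteins (cannot split one protein)")
  }
  graphs <- lapply(dataset, `[[`, "graph")
  labels <- lapply(dataset, `[[`, "labels")
  modes <- unique(vapply(graphs, function(g) g$meta$mode, ""))
  if (length(modes) != 1 || modes != config$mode) {
    stop_validation(sprintf("graph mode(s) %s do not match config mode %s",
      paste(modes, collapse = "/"), config$mode))
  }
  schemes <- unique(vapply(labels, function(l) label_scheme(l) %||% "", ""))
  if (length(schemes) != 1 || schemes != config$scheme) {
    stop_validation("label scheme(s) do not match the config scheme")
  }
  np <- length(dataset)
  with_seed(config$seed, {
    perm <- sample.int(np)
    n_val <- max(1L, round(config$val_fraction * np))
    val_idx <- perm[seq_len(n_val)]
    train_idx <- setdiff(perm, val_idx)
    train_graphs <- graphs[train_idx]
    train_labels <- labels[train_idx]
    if (!is.null(config$ablation_augment)) {
      for (frac in config$ablation_augment) {
        for (i in train_idx) {
          s <- dataset[[i]]$structure
          if (is.null(s)) {
            stop_validation("ablation_augment needs a `structure` field in every dataset entry")
          }
          sa <- ablate_residues(s, frac)
          kept <- attr(sa, "ablation_kept")
          train_graphs[[length(train_graphs) + 1]] <- refeaturize_like(graphs[[i]], sa)
          train_labels[[length(train_labels) + 1]] <- label_vector(labels[[i]])[kept]
        }
      }
    }
    train <- assemble_block(train_graphs, train_labels, config$include_res_type)
    val <- assemble_block(graphs[val_idx], labels[val_idx], config$include_res_type)
    ns <- norm_stats(train)
    train <- apply_norm(train, ns)
    val <- apply_norm(val, ns)

    d <- config$n_classes
    class_w <- if (is.null(config$class_weights)) {
      rep(1, d)
    } else if (identical(config$class_weights, "balanced")) {
      freq <- tabulate(train$y + 1L, nbins = d)
      w <- ifelse(freq > 0, sum(freq) / (d * freq), 0)
      w
    } else {
      if (length(config$class_weights) != d) stop_validation("class_weights length must equal the class count")
      config$class_weights
    }

    params <- init_params(config, node_dim = ncol(train$X), edge_dim = ncol(train$E))
    mstate <- map_params(params, function(x) x * 0)
    vstate <- map_params(params, function(x) x * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate

    history <- vector("list", config$epochs)
    best <- list(f1 = -Inf, params = params, epoch = 0L)
    stall <- 0L
    for (epoch in seq_len(config$epochs)) {
      fwd <- mpn_forward_block(params, train, config, keep_cache = TRUE)
      bwd <- mpn_backward_block(params, train, config, fwd, class_w)
      step <- epoch
      mstate <- walk_params(mstate, bwd$grads, function(m, g) b1 * m + (1 - b1) * g)
      vstate <- walk_params(vstate, bwd$grads, function(v, g) b2 * v + (1 - b2) * g^2)
      mhat_scale <- 1 / (1 - b1^step)
      vhat_scale <- 1 / (1 - b2^step)
      upd <- walk_params(mstate, vstate, function(m, v) {
        lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
      })
      params <- walk_params(params, upd, function(p, u) p - u)

      val_p <- mpn_forward_block(params, val, config)$P
      val_pred <- max.col(val_p, ties.method = "first") - 1L
      f1 <- macro_prf(val$y, val_pred, scheme = config$scheme)$macro_f1
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = bwd$loss, val_macro_f1 = f1
      )
      if (f1 > best$f1 + 1e-12) {
        best <- list(f1 = f1, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (verbose && epoch %% 10 == 0) {
        message(sprintf("epoch %3d  loss %.4f  val F1 %.4f", epoch, bwd$loss, f1))
      }
      if (stall >= config$patience) break
    }
    structure(
      list(
        params = best$params, config = config,
        history = dplyr::bind_rows(history),
        best_epoch = best$epoch, best_val_f1 = best$f1,
        norm = ns, node_dim = ncol(train$X), edge_dim = ncol(train$E),
        n_train_proteins = length(train_idx), n_val_proteins = n_val
      ),
      class = "mpn_model"
    )
  })
}

#' @export
print.mpn_model <- function(x, ...) {
  cat(sprintf(
    "# mpn_model (%s, mode %s): hidden %d, best val macro F1 %.4f at epoch %d/%d\n",
    x$config$scheme, x$config$mode, x$config$hidden_dim,
    x$best_val_f1, x$best_epoch, nrow(x$history)
  ))
  invisible(x)
}

#' @export
tidy.mpn_model <- function(x, ...) x$history

#' @export
glance.mpn_model <- function(x, ...) {
  tibble::tibble(
    scheme = x$config$scheme, mode = x$config$mode,
    hidden_dim = x$config$hidden_dim, epochs_run = nrow(x$history),
    best_epoch = x$best_epoch, best_val_macro_f1 = x$best_val_f1,
    n_train_proteins = x$n_train_proteins, n_val_proteins = x$n_val_proteins
  )
}

graph_block_for_model <- function(model, g) {
  if (g$meta$mode != model$config$mode) {
    stop_validation(sprintf(
      "graph mode '%s' does not match the model's '%s'", g$meta$mode, model$config$mode
    ))
  }
  block <- assemble_block(list(g), NULL, model$config$include_res_type)
  if (ncol(block$X) != model$node_dim || ncol(block$E) != model$edge_dim) {
    stop_validation("feature dimensions do not match the trained model")
  }
  apply_norm(block, model$norm)
}

#' Class probabilities of a graph's residues under a trained model
#'
#' @param model An `mpn_model`.
#' @param g A featurized `residue_graph` of the model's mode.
#' @return Matrix (`n_nodes` x `n_classes`) of per-residue probabilities;
#'   rows sum to 1.
#' @export
mpn_forward <- function(model, g) {
  block <- graph_block_for_model(model, g)
  mpn_forward_block(model$params, block, model$config)$P
}

#' Predict per-residue secondary-structure classes
#'
#' Argmax of the forward probabilities; exact probability ties resolve to
#' the smallest class id.
#'
#' @param object An `mpn_model`.
#' @param g A featurized `residue_graph` matching the model's mode.
#' @param type `"labels"` for an `ss_labels` tibble, `"prob"` for the
#'   probability matrix.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.mpn_model <- function(object, g, type = c("labels", "prob"), ...) {
  type <- match.arg(type)
  P <- mpn_forward(object, g)
  if (type == "prob") return(P)
  new_ss_labels(
    tibble::tibble(
      res_id = g$nodes$res_id, chain = g$nodes$chain, resnum = g$nodes$resnum,
      class_id = max.col(P, ties.method = "first") - 1L
    ),
    scheme = object$config$scheme
  )
}
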