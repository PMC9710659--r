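# First-order-statistics baseline.
#
# Along a strand the backbone extends; along a helix it spirals. The
# neighbourhood mean of the edge feature triple (d, cos_phi, cos_psi)
# already separates these local geometries, so a plain k-nearest-neighbour
# classifier on those three per-node statistics makes a solid
# sequence-agnostic baseline. An optional variant appends elementwise
# variances (doubling the feature dimension).

#' Per-node first-order-statistics features
#'
#' Elementwise mean (and optionally variance) of the unmasked incoming
#' directed edge features of each node. Isolated nodes get zeros and a mask
#' flag.
#'
#' @param g A `residue_graph` with features attached.
#' @param include_variance Append elementwise variances (sample variance,
#'   0 for a single observation)?
#' @return Tibble with `res_id`, one column per statistic, and `isolated`.
#' @export
fos_features <- function(g, include_variance = FALSE) {
  if (!isTRUE(g$meta$features_attached)) stop_validation("attach_edge_features() first")
  e <- g$edges
  n <- nrow(g$nodes)
  channels <- g$meta$feature_channels
  stat_cols <- list()
  for (ch in channels) {
    ok <- if (ch == "d") rep(TRUE, nrow(e)) else e[[paste0(sub("^cos_", "", ch), "_ok")]]
    vals <- e[[ch]][ok]
    tos <- e$to[ok]
    mu <- rep(0, n)
    sg <- rep(0, n)
    if (length(vals) > 0) {
      agg_mu <- tapply(vals, tos, mean)
      mu[as.integer(names(agg_mu))] <- agg_mu
      agg_sg <- tapply(vals, tos, function(v) if (length(v) > 1) var(v) else 0)
      sg[as.integer(names(agg_sg))] <- agg_sg
    }
    stat_cols[[paste0("mean_", ch)]] <- mu
    if (include_variance) stat_cols[[paste0("var_", ch)]] <- sg
  }
  out <- tibble::tibble(res_id = g$nodes$res_id)
  for (nm in names(stat_cols)) out[[nm]] <- stat_cols[[nm]]
  out$isolated <- !(g$nodes$res_id %in% e$to)
  out
}

#' Fit the FOS k-nearest-neighbour classifier
#'
#' Stores the training features and labels; prediction is a majority vote
#' among the `k_classifier` nearest training points in raw Euclidean
#' feature space. Vote ties resolve to the smallest class id and neighbour
#' distance ties to the smallest training index, so prediction is fully
#' deterministic.
#'
#' @param features Data frame of numeric features (e.g. [fos_features()]
#'   output; `res_id`/`isolated` columns are ignored).
#' @param labels Integer class ids aligned to `features` rows, or an
#'   `ss_labels` tibble.
#' @param k_classifier Neighbourhood size of the classifier (default 20,
#'   the best noise-free setting; 60 is the better choice on noisy inputs).
#' @param scheme Labelling scheme (taken from `labels` when it carries one).
#' @return An object of class `fos_model`.
#' @export
fos_fit <- function(features, labels, k_classifier = 20, scheme = NULL) {
  X <- fos_feature_matrix(features)
  if (inherits(labels, "ss_labels")) {
    scheme <- scheme %||% label_scheme(labels)
    y <- labels$class_id
  } else {
    y <- as.integer(labels)
  }
  scheme <- scheme %||% "alpha-beta-other"
  if (length(y) != nrow(X)) stop_validation("features and labels lengths differ")
  if (!is_count(k_classifier, min = 1)) stop_validation("`k_classifier` must be a positive integer")
  if (nrow(X) < k_classifier) {
    stop_validation(sprintf(
      "k_classifier = %d exceeds the %d training nodes", k_classifier, nrow(X)
    ))
  }
  d <- n_classes(scheme)
  if (any(y < 0 | y >= d)) stop_validation("class ids out of range for the scheme")
  structure(
    list(X = X, y = y, k = as.integer(k_classifier), scheme = scheme),
    class = "fos_model"
  )
}

fos_feature_matrix <- function(features) {
  df <- tibble::as_tibble(features)
  df <- df[setdiff(names(df), c("res_id", "isolated"))]
  X <- as.matrix(df)
  if (!is.numeric(X) || nrow(X) == 0) stop_validation("`features` must contain numeric feature columns")
  X
}

#' @export
print.fos_model <- function(x, ...) {
  cat(sprintf(
    "# fos_model: %d training nodes, %d features, k = %d, scheme = %s\n",
    nrow(x$X), ncol(x$X), x$k, x$scheme
  ))
  invisible(x)
}

#' Predict classes with a fitted FOS model
#'
#' @param object A `fos_model`.
#' @param newdata Feature data frame ([fos_features()] output) for the
#'   nodes to classify.
#' @param ... Unused.
#' @return Integer vector of predicted class ids.
#' @export
predict.fos_model <- function(object, newdata, ...) {
  Xt <- fos_feature_matrix(newdata)
  if (ncol(Xt) != ncol(object$X)) stop_validation("feature dimension mismatch with the training set")
  d2 <- outer(rowSums(Xt^2), rowSums(object$X^2), "+") - 2 * Xt %*% t(object$X)
  k <- object$k
  d <- n_classes(object$scheme)
  apply(d2, 1, function(row) {
    nb <- head(order(row), k) # ties: smallest training index
    votes <- tabulate(object$y[nb] + 1L, nbins = d)
    which.max(votes) - 1L # ties: smallest class id
  })
}
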