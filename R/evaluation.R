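# Evaluation: macro metrics, boundary-error localisation, element statistics.
#
# Macro averaging divides by the full class count d of the scheme, counting
# classes absent from the test set as 0 — deliberately conservative, and
# consistent across prediction tasks with different d.

label_vector <- function(x) {
  if (inherits(x, "ss_labels") || is.data.frame(x)) {
    as.integer(x$class_id)
  } else {
    as.integer(x)
  }
}

infer_scheme <- function(x, scheme = NULL) {
  scheme %||% (if (inherits(x, "ss_labels")) label_scheme(x) else NULL)
}

#' Macro precision, recall and F1
#'
#' Per-class precision `P_i` (correct assignments to class i over all
#' assignments to class i) and recall `R_i` (correct over true members),
#' with the 0 convention for empty denominators; macro averages run over
#' all `d` classes of the scheme, absent classes included. `F1 = 2PR/(P+R)`
#' (0 when `P + R = 0`).
#'
#' @param true,pred `ss_labels` tibbles or integer class-id vectors of equal
#'   length.
#' @param scheme Labelling scheme; inferred from `true`/`pred` when they
#'   carry one.
#' @return A `metrics_report`: per-class table, macro P/R/F1, confusion
#'   matrix. Use [glance()] for a one-row summary and [tidy()] for the
#'   per-class table.
#' @export
macro_prf <- function(true, pred, scheme = NULL) {
  scheme <- infer_scheme(true, scheme) %||% infer_scheme(pred, scheme)
  if (is.null(scheme)) stop_validation("supply `scheme` (labels carry none)")
  ts <- infer_scheme(true)
  ps <- infer_scheme(pred)
  if (!is.null(ts) && !is.null(ps) && ts != ps) stop_validation("true/pred schemes differ")
  yt <- label_vector(true)
  yp <- label_vector(pred)
  if (length(yt) != length(yp)) stop_validation("true/pred lengths differ")
  d <- n_classes(scheme)
  lv <- 0:(d - 1)
  conf <- table(
    true = factor(yt, levels = lv),
    pred = factor(yp, levels = lv)
  )
  conf <- unclass(conf)
  tp <- diag(conf)
  n_true <- rowSums(conf)
  n_assigned <- colSums(conf)
  recall <- ifelse(n_true > 0, tp / n_true, 0)
  precision <- ifelse(n_assigned > 0, tp / n_assigned, 0)
  P <- mean(precision)
  R <- mean(recall)
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(
    list(
      per_class = tibble::tibble(
        class_id = lv, precision = unname(precision), recall = unname(recall),
        n_true = unname(n_true), n_assigned = unname(n_assigned)
      ),
      macro_precision = P, macro_recall = R, macro_f1 = f1,
      accuracy = sum(tp) / max(1, length(yt)),
      confusion = conf, d = d, scheme = scheme, n = length(yt)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "# metrics_report (%s, %d classes, n = %d)\n#   macro P = %.4f  R = %.4f  F1 = %.4f  accuracy = %.4f\n",
    x$scheme, x$d, x$n, x$macro_precision, x$macro_recall, x$macro_f1, x$accuracy
  ))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    macro_precision = x$macro_precision, macro_recall = x$macro_recall,
    macro_f1 = x$macro_f1, accuracy = x$accuracy, n = x$n,
    d = x$d, scheme = x$scheme
  )
}

#' Maximal-run secondary-structure element spans
#'
#' Segments the label sequence into maximal runs and returns the runs whose
#' class is a helix or strand class under the scheme, as 0-based half-open
#' `[start, end)` index spans.
#'
#' @param labels `ss_labels` or integer class-id vector.
#' @param scheme Labelling scheme (inferred when possible).
#' @return Tibble with `ss_class` (`"alpha"`/`"beta"`), `start`, `end`.
#' @export
element_spans <- function(labels, scheme = NULL) {
  scheme <- infer_scheme(labels, scheme)
  if (is.null(scheme)) stop_validation("supply `scheme`")
  y <- label_vector(labels)
  ec <- element_class_ids(scheme)
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cls <- names(ec)[match(r$values, ec)]
  keep <- !is.na(cls)
  tibble::tibble(ss_class = cls[keep], start = starts[keep], end = ends[keep])
}

#' Histogram of prediction errors by distance to element extremity
#'
#' For each misclassified residue lying inside a true helix/strand element,
#' the distance to the nearest element extremity is `w = 1 + min(offset
#' from start, offset from end)` (so the first or last residue has
#' `w = 1`). Errors are binned at `w = 1 .. w_max`, deeper errors in an
#' `"interior"` bucket, and misclassifications outside any element in an
#' `"outside"` bucket.
#'
#' @param true,pred `ss_labels` or integer class-id vectors (same scheme).
#' @param w_max Largest explicit `w` bin (default 2).
#' @return Tibble with `bucket` and `errors`, all buckets present.
#' @export
boundary_error_profile <- function(true, pred, w_max = 2, scheme = NULL) {
  scheme <- infer_scheme(true, scheme) %||% infer_scheme(pred, scheme)
  if (is.null(scheme)) stop_validation("supply `scheme`")
  if (!is_count(w_max, min = 1)) stop_validation("`w_max` must be a positive integer")
  yt <- label_vector(true)
  yp <- label_vector(pred)
  if (length(yt) != length(yp)) stop_validation("true/pred lengths differ")
  spans <- element_spans(yt, scheme = scheme)
  wrong <- which(yt != yp) - 1L # 0-based positions
  buckets <- c(as.character(seq_len(w_max)), "interior", "outside")
  counts <- setNames(rep(0L, length(buckets)), buckets)
  in_element <- rep(FALSE, length(yt))
  if (nrow(spans) > 0) {
    for (r in seq_len(nrow(spans))) {
      in_element[(spans$start[r] + 1):spans$end[r]] <- TRUE
    }
  }
  for (pos in wrong) {
    if (!in_element[pos + 1]) {
      counts["outside"] <- counts["outside"] + 1L
      next
    }
    sp <- spans[spans$start <= pos & pos < spans$end, ][1, ]
    w <- 1L + min(pos - sp$start, sp$end - 1L - pos)
    key <- if (w <= w_max) as.character(w) else "interior"
    counts[key] <- counts[key] + 1L
  }
  tibble::tibble(bucket = factor(buckets, levels = buckets), errors = unname(counts))
}

#' Element count and mean length per secondary-structure class
#'
#' Maximal-run segmentation; Other runs are excluded. A class with no
#' elements reports count 0 and mean length 0.
#'
#' @param labels `ss_labels` or integer class-id vector.
#' @param scheme Labelling scheme (inferred when possible).
#' @return Tibble with `ss_class`, `n_elements`, `mean_length`.
#' @export
element_stats <- function(labels, scheme = NULL) {
  scheme <- infer_scheme(labels, scheme)
  if (is.null(scheme)) stop_validation("supply `scheme`")
  spans <- element_spans(labels, scheme = scheme)
  classes <- names(element_class_ids(scheme))[!is.na(element_class_ids(scheme))]
  purrr::map_dfr(classes, function(cl) {
    sp <- spans[spans$ss_class == cl, ]
    tibble::tibble(
      ss_class = cl,
      n_elements = nrow(sp),
      mean_length = if (nrow(sp) > 0) mean(sp$end - sp$start) else 0
    )
  })
}

#' Relabel element extremities as Other
#'
#' Removes the first and last `w` residues of every helix/strand element
#' from the element (relabelling them Other); elements shorter than
#' `2w + 1` dissolve entirely. Used to re-score predictions with the
#' ambiguous limit residues excluded from the element definition.
#'
#' @param labels `ss_labels` or integer class-id vector.
#' @param w Number of extremity residues to strip per side (>= 1).
#' @param scheme Labelling scheme (inferred when possible).
#' @return Labels of the same type with trimmed elements.
#' @export
trim_element_limits <- function(labels, w = 1, scheme = NULL) {
  scheme <- infer_scheme(labels, scheme)
  if (is.null(scheme)) stop_validation("supply `scheme`")
  if (!is_count(w, min = 1)) stop_validation("`w` must be a positive integer")
  y <- label_vector(labels)
  other <- other_class_id(scheme)
  spans <- element_spans(y, scheme = scheme)
  for (r in seq_len(nrow(spans))) {
    s0 <- spans$start[r]
    e0 <- spans$end[r]
    if (e0 - s0 < 2 * w + 1) {
      y[(s0 + 1):e0] <- other
    } else {
      y[(s0 + 1):(s0 + w)] <- other
      y[(e0 - w + 1):e0] <- other
    }
  }
  if (inherits(labels, "ss_labels") || is.data.frame(labels)) {
    labels$class_id <- y
    labels
  } else {
    y
  }
}
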