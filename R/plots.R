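# ggplot2 visualisations of result objects.

#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_class,
    cols = c("precision", "recall"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$class_id), y = .data$value, fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$macro_f1, linetype = "dashed") +
    ggplot2::labs(
      x = "class id", y = NULL,
      title = sprintf("Per-class precision/recall (%s)", object$scheme),
      subtitle = sprintf("macro F1 = %.3f (dashed)", object$macro_f1)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mpn_model <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$history,
    cols = c("train_loss", "val_macro_f1"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "epoch", y = NULL, title = "Training history",
      subtitle = sprintf("best validation macro F1 = %.3f at epoch %d",
        object$best_val_f1, object$best_epoch)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a boundary-error histogram
#'
#' @param profile Output of [boundary_error_profile()].
#' @return A ggplot object.
#' @export
plot_boundary_errors <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bucket, y = .data$errors)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "distance to element extremity (w)", y = "misclassified residues",
      title = "Where errors sit inside secondary-structure elements"
    ) +
    ggplot2::theme_minimal()
}

#' Plot Monte-Carlo angle error against the dihedral angle
#'
#' @param sim Output of [monte_carlo_omega_error()].
#' @return A ggplot object.
#' @export
plot_omega_error <- function(sim) {
  ggplot2::ggplot(sim, ggplot2::aes(
    x = .data$omega, y = .data$mean_abs_error,
    colour = factor(.data$eta2), group = factor(.data$eta2)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(omega ~ "(degrees)"),
      y = "mean |error| on recovered angle (degrees)",
      colour = expression(eta[2]),
      title = "Angle error induced by cosine noise"
    ) +
    ggplot2::theme_minimal()
}
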