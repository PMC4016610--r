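#' Plot an ROC curve
#'
#' ROC curve with the TCR-optimal operating point marked.
#'
#' @param object An `fs_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fs_roc <- function(object, ...) {
  best <- object$curve[object$curve$threshold == object$best_threshold, ][1, ]
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.4f; best threshold %.4g (TCR %.3f)",
                      object$auc, object$best_threshold, object$best_tcr)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a 2-D view of a structure-space map
#'
#' Scatter of two coordinate axes, optionally coloured by clade.
#'
#' @param object An `fs_config`.
#' @param dims Two axis indices to display (default `c(1, 2)`).
#' @param partition Optional `fs_partition` used to colour points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fs_config <- function(object, dims = c(1, 2), partition = NULL, ...) {
  stopifnot(length(dims) == 2, max(dims) <= object$dim)
  df <- tidy.fs_config(object)
  df$x <- object$coords[, dims[1]]
  df$y <- object$coords[, dims[2]]
  if (!is.null(partition)) {
    df <- dplyr::left_join(df, tibble::as_tibble(partition), by = "id")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$cluster)) +
      ggplot2::guides(colour = "none")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  }
  p + ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = sprintf("dim %d", dims[1]), y = sprintf("dim %d", dims[2]),
                  title = sprintf("%s map (%dD), stress %.4g",
                                  object$method, object$dim, object$stress)) +
    ggplot2::theme_minimal()
}

#' Plot a degree histogram and its power-law fit
#'
#' Log-log scatter of the non-empty histogram bins with the fitted line.
#'
#' @param object An `fs_powerlaw` from [degree_powerlaw_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fs_powerlaw <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$center, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$exponent, intercept = object$intercept,
                         colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "alignment partners per structure", y = "frequency",
                  title = sprintf("power-law fit: slope %.2f, R² = %.3f",
                                  object$exponent, object$r_squared)) +
    ggplot2::theme_minimal()
}
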