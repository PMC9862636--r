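#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot spectra colored by class
#'
#' @param object A `spectra_set`.
#' @param alpha Line transparency.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectra_set <- function(object, alpha = 0.4, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$absorbance,
                                   group = .data$sample_id,
                                   color = .data$label)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance", color = "class") +
    ggplot2::theme_minimal()
}

#' Plot a synchronous or asynchronous 2D correlation map
#'
#' @param object A `twodcos` object.
#' @param which `"sync"` or `"async"`.
#' @param ... Unused.
#' @return A ggplot raster of the map.
#' @export
autoplot.twodcos <- function(object, which = c("sync", "async"), ...) {
  which <- match.arg(which)
  df <- tidy(object)
  df$value <- df[[which]]
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda1, .data$lambda2,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(lambda[1] ~ "(nm)"),
                  y = expression(lambda[2] ~ "(nm)"),
                  fill = which) +
    ggplot2::theme_minimal()
}

#' Radar-style aquagram plot
#'
#' @param object An `aquagram`.
#' @param ... Unused.
#' @return A ggplot in polar coordinates.
#' @export
autoplot.aquagram <- function(object, ...) {
  df <- dplyr::mutate(object, band_label = factor(.data$band_label,
                                                  levels = unique(.data$band_label)))
  ggplot2::ggplot(df, ggplot2::aes(.data$band_label, .data$value,
                                   group = .data$class, color = .data$class)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "normalized absorbance", color = "class") +
    ggplot2::theme_minimal()
}

#' Scatter plot of an embedding
#'
#' @param object An `spc_embedding`.
#' @param ... Unused.
#' @return A ggplot of the first two embedding dimensions.
#' @export
autoplot.spc_embedding <- function(object, ...) {
  df <- object$coords
  lab <- function(j) {
    if (!is.null(object$explained_variance) && j <= length(object$explained_variance)) {
      sprintf("PC%d (%.1f%%)", j, 100 * object$explained_variance[j])
    } else {
      sprintf("%s dim %d", object$method, j)
    }
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2, color = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1), y = lab(2), color = "class") +
    ggplot2::theme_minimal()
}

#' Training-history curves of a deep fit
#'
#' @param object A `deep_fit`.
#' @param ... Unused.
#' @return A ggplot with loss and accuracy panels over epochs.
#' @export
autoplot.deep_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param roc The `roc` tibble from [roc_auc()].
#' @param auc Optional AUC to annotate.
#' @return A ggplot.
#' @export
plot_roc <- function(roc, auc = NULL) {
  p <- ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
  if (!is.null(auc)) {
    p <- p + ggplot2::annotate("text", x = 0.75, y = 0.1,
                               label = sprintf("AUC = %.4f", auc))
  }
  p
}

#' Out-of-bag error sweep plot for a random forest fit
#'
#' @param fit An `rf_fit` with a sweep.
#' @return A ggplot of OOB error against tree count.
#' @export
plot_oob_sweep <- function(fit) {
  stopifnot(inherits(fit, "rf_fit"), !is.null(fit$oob_curve))
  ggplot2::ggplot(fit$oob_curve, ggplot2::aes(.data$n_trees, .data$oob_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of trees", y = "OOB error rate") +
    ggplot2::theme_minimal()
}
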