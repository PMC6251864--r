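#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object An `m5c_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot m5c_roc
#' @export
autoplot.m5c_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the intra-/inter-tissue AUC matrix
#'
#' @param object An `m5c_tissue_matrix` from [cross_tissue_benchmark()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot m5c_tissue_matrix
#' @export
autoplot.m5c_tissue_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test_tissue,
                                   y = .data$predictor_tissue,
                                   fill = .data$auc)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$auc)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#F7FBFF", high = "#08519C",
                                 limits = c(0.5, 1), oob = scales_squish) +
    ggplot2::labs(x = "Test set tissue", y = "Predictor tissue",
                  fill = "AUC",
                  title = "Intra- vs inter-tissue prediction performance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

# clamp out-of-range fills instead of dropping them (avoids a scales dep
# at the package surface; same behaviour as scales::squish)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
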