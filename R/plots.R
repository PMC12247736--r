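#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-segment morphology of a vessel tree
#'
#' Scatter of segment tortuosity against segment length, point size by mean
#' radius — the quick visual check that a decomposition looks vascular
#' (tortuosity >= 1, radii positive, no giant fragments).
#'
#' @param object a `vessel_tree` from [decompose_skeleton()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vessel_tree <- function(object, ...) {
  segs <- tidy(object)
  segs <- segs[!is.na(segs$tortuosity), , drop = FALSE]
  ggplot2::ggplot(segs, ggplot2::aes(x = .data$length_mm,
                                     y = .data$tortuosity,
                                     size = .data$mean_radius_mm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "segment length (mm)", y = "tortuosity",
                  size = "mean radius (mm)") +
    ggplot2::theme_minimal()
}

#' Plot out-of-fold predictions of a cross-validated model
#'
#' Observed vs predicted over the pooled out-of-fold predictions, with the
#' identity line; the pooled coefficient of determination is shown in the
#' subtitle.
#'
#' @param object a `vm_crossval` from [crossval_r2()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vm_crossval <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "observed", y = "out-of-fold prediction",
      subtitle = sprintf("%d-fold cross-validated R² = %.3f",
                         object$k, object$r2)) +
    ggplot2::theme_minimal()
}
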