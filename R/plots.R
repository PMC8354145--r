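#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a P/E curve with its replicate band
#'
#' Mean predicted-to-expected ratio against the logistic score, the 95%
#' replicate band, and the random-chance line at F = 1.
#'
#' @param object a `pe_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pe_curve <- function(object, ...) {
  w <- object$windows
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$midpoint, y = .data$f_mean))
  if (!all(is.na(w$lo))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                                  fill = "grey80")
  }
  p +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "orange") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "logistic score (window midpoint)",
                  y = "predicted / expected",
                  subtitle = sprintf("continuous Boyce index %.3f", object$boyce))
}

#' Plot a grid layer
#' @param object a `grid_layer`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.grid_layer <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$name, x = NULL, y = NULL)
}

#' Plot per-radius AIC profiles from a scale selection
#' @param object a `scale_selection` (from [optimize_scale()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.scale_selection <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$radius, y = .data$aic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::labs(title = attr(object, "variable"), x = "radius (m)",
                  y = "AIC", colour = "selected")
}

#' Plot response curves
#' @param curves tibble from [response_curves()].
#' @return a ggplot faceted by variable.
#' @export
plot_response_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$value, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = "covariate value", y = "logistic output")
}
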