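#' @export
autoplot.regional_synthesis <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$age, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95, ymax = .data$upper95),
                         fill = "grey80") +
    ggplot2::geom_line(linetype = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$running_mean5)) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (cal ka BP)", y = "anomaly")
}

#' Plot held-out versus observed values of a cross-validation
#'
#' @param object An `hblock_cv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hblock_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(
      title = sprintf("%s, %s: h = %g km, R2 = %.2f",
                      object$method, object$target, object$h_km, object$r2),
      x = "observed", y = "held-out prediction")
}
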