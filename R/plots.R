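#' Plot a growth fit
#'
#' Measured values and the fitted exponential on a log-scaled y axis.
#'
#' @param object A `growth_fit` from [fit_exponential()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_function(
      fun = function(t) object$v0 * exp(object$k * t),
      colour = "firebrick"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (h)", y = "value",
      title = sprintf("Exponential fit: PDT = %.2f h", object$pdt)
    )
}

#' Plot a breakpoint fit
#'
#' Thickness-versus-radius data with the fitted one- or two-segment line.
#'
#' @param object A `breakpoint_fit` from [fit_breakpoint()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.breakpoint_fit <- function(object, ...) {
  df <- object$data
  pred <- function(r) {
    object$intercept + object$slope1 * r +
      (if (object$single_line) 0 else {
        (object$slope2 - object$slope1) * pmax(r - object$breakpoint, 0)
      })
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$radius,
                                        y = .data$thickness)) +
    ggplot2::geom_point() +
    ggplot2::geom_function(fun = pred, colour = "firebrick") +
    ggplot2::labs(x = "lumen radius (um)", y = "layer thickness (um)")
  if (!object$single_line) {
    p <- p + ggplot2::geom_vline(xintercept = object$breakpoint,
                                 linetype = "dashed")
  }
  p
}

#' Plot normalized volume series
#'
#' One normalized growth curve per tracked object, log-scaled.
#'
#' @param series A tibble with `time`, a normalized value column and a
#'   grouping id column.
#' @param value Column name of the normalized value. Default
#'   `"norm_volume"`.
#' @param id Column name of the object id. Default `"capsule_id"`.
#' @return A ggplot.
#' @export
plot_volume_series <- function(series, value = "norm_volume",
                               id = "capsule_id") {
  ggplot2::ggplot(series, ggplot2::aes(
    x = .data$time, y = .data[[value]],
    group = factor(.data[[id]]), colour = factor(.data[[id]])
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "V / V(0)", colour = "object")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
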