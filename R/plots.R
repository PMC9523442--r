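#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stress-strain curve
#'
#' @param object A `stress_strain` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stress_strain <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$strain, y = .data$stress_Pa)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "engineering strain",
      y = "nominal stress [Pa]",
      title = sprintf("%s, %g mm/min", attr(object, "mode"),
                      attr(object, "velocity_mm_per_min"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a van der Waals fit over its data
#'
#' Measured curve as points, fitted model as a line, with the linear-regime
#' slope for comparison.
#'
#' @param object A `vdw_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vdw_fit <- function(object, ...) {
  curve <- tibble::as_tibble(object$curve)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$strain,
                                           y = .data$stress_Pa)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::labs(x = "engineering strain", y = "nominal stress [Pa]") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- seq(0, max(curve$strain), length.out = 200)
    model <- vdw_curve(grid, object$params, mode = attr(object$curve, "mode"))
    p <- p +
      ggplot2::geom_line(data = tibble::as_tibble(model),
                         colour = "steelblue", linetype = "dashed") +
      ggplot2::ggtitle(sprintf("E(vdW) = %.0f Pa, E(linear) = %.0f Pa",
                               object$young_vdw_Pa, object$young_linear_Pa))
  }
  p
}

#' Plot an Ussing-chamber trace
#'
#' Signal against time with inhibitor events marked.
#'
#' @param object An `ussing_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ussing_trace <- function(object, ...) {
  sig <- ussing_signal_col(object)
  ylab <- if (sig == "v_te_mV") "V_te [mV]" else "I_sc [uA/cm2]"
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data[[sig]])) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time [s]", y = ylab) +
    ggplot2::theme_minimal()
  ev <- ussing_events(object)
  if (nrow(ev)) {
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$time_s),
                                 linetype = "dotted", colour = "firebrick")
  }
  p
}
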