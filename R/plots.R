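# ggplot2 autoplot methods for the package's result types.

#' Plot a flow waveform
#'
#' @param object A [flow_waveform()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_waveform
#' @export
autoplot.flow_waveform <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$time_s, y = .data$flow_lpm)
  ) +
    ggplot2::geom_line(color = "#2c6e91") +
    ggplot2::labs(
      x = "time (s)", y = "flow (L/min)",
      title = sprintf("Flow waveform (period %.3g s)", wave_period(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a step schedule
#'
#' @param object A [step_schedule()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot step_schedule
#' @export
autoplot.step_schedule <- function(object, ...) {
  df <- tibble::tibble(
    time_s = c(0, cumsum(object$duration_s)),
    flow_lpm = c(object$flow_lpm, dplyr::last(object$flow_lpm))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$flow_lpm)) +
    ggplot2::geom_step(color = "#91452c") +
    ggplot2::labs(
      x = "time (s)", y = "flow (L/min)",
      title = sprintf("Pump step schedule (%d steps per cycle)", nrow(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a constant-flow calibration fit
#'
#' Trials as points, the fitted correction line, and the ideal identity line
#' (dashed) for reference.
#'
#' @param object A `flow_calibration` from [fit_linear_calibration()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_calibration
#' @export
autoplot.flow_calibration <- function(object, ...) {
  ggplot2::ggplot(
    object$trials,
    ggplot2::aes(x = .data$set_flow_lpm, y = .data$measured_flow_lpm)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      color = "#2c6e91"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "set flow (L/min)", y = "measured flow (L/min)",
      title = sprintf(
        "Constant-flow calibration: y = %.3f x %+.3f (r^2 = %.4f)",
        object$slope, object$intercept, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a thermostat heating trace
#'
#' Temperature vs. time with heater state shaded along the time axis.
#'
#' @param object A `thermal_trace` from [simulate_heating()].
#' @param setpoint_c,deadband_c Optional setpoint band to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thermal_trace
#' @export
autoplot.thermal_trace <- function(object, setpoint_c = 37, deadband_c = 1, ...) {
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$time_s, y = .data$temp_c)
  ) +
    ggplot2::geom_line(ggplot2::aes(color = .data$heater_on, group = 1)) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#c23b22", `FALSE` = "#2c6e91"),
      labels = c(`TRUE` = "on", `FALSE` = "off"), name = "heater"
    ) +
    ggplot2::labs(
      x = "time (s)", y = "temperature (degC)",
      title = "Reservoir heating under bang-bang control"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(setpoint_c)) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = -Inf, xmax = Inf,
      ymin = setpoint_c - deadband_c / 2, ymax = setpoint_c + deadband_c / 2,
      alpha = 0.15, fill = "grey40"
    )
  }
  p
}

#' @importFrom rlang .data
NULL
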