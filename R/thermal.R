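# Lumped reservoir heating dynamics with bang-bang (hysteresis) control,
# emulating the sous-vide heater holding the loop at body temperature.

#' Lumped thermal model of the heated reservoir
#'
#' A single well-mixed water volume with heater input and Newtonian loss to
#' ambient: `m c dT/dt = P u - k (T - ambient)`, `u` the heater state.
#' Defaults describe the loop's 3 L heating-test tank with a 1 kW sous-vide
#' element and a 5 W/degC loss coefficient.
#'
#' @param volume_l Water volume, liters (> 0).
#' @param heater_power_w Heater power when on, watts (> 0).
#' @param loss_coefficient_w_per_c Heat-loss coefficient to ambient,
#'   W/degC (>= 0).
#' @param ambient_c Ambient temperature, degC.
#' @param specific_heat_j_per_kg_c Specific heat, J/(kg degC) (> 0).
#' @param density_kg_per_l Fluid density, kg/L (> 0).
#'
#' @return A list of class `thermal_model`.
#' @export
thermal_model <- function(volume_l = 3,
                          heater_power_w = 1000,
                          loss_coefficient_w_per_c = 5,
                          ambient_c = 20,
                          specific_heat_j_per_kg_c = 4186,
                          density_kg_per_l = 1) {
  check_scalar_number(volume_l, "volume_l", positive = TRUE)
  check_scalar_number(heater_power_w, "heater_power_w", positive = TRUE)
  check_scalar_number(loss_coefficient_w_per_c, "loss_coefficient_w_per_c", non_negative = TRUE)
  check_scalar_number(ambient_c, "ambient_c")
  check_scalar_number(specific_heat_j_per_kg_c, "specific_heat_j_per_kg_c", positive = TRUE)
  check_scalar_number(density_kg_per_l, "density_kg_per_l", positive = TRUE)
  structure(
    list(
      volume_l = volume_l,
      heater_power_w = heater_power_w,
      loss_coefficient_w_per_c = loss_coefficient_w_per_c,
      ambient_c = ambient_c,
      specific_heat_j_per_kg_c = specific_heat_j_per_kg_c,
      density_kg_per_l = density_kg_per_l
    ),
    class = "thermal_model"
  )
}

#' Bang-bang thermostat controller
#'
#' Hysteresis control around the setpoint: the heater switches on below
#' `setpoint - deadband/2`, off above `setpoint + deadband/2`, and holds its
#' state inside the band. Defaults encode the loop's 37 +/- 1 degC operating
#' criterion.
#'
#' @param setpoint_c Setpoint temperature, degC.
#' @param deadband_c Full hysteresis band width, degC (> 0).
#' @return A list of class `thermostat_controller`.
#' @export
thermostat_controller <- function(setpoint_c = 37, deadband_c = 1) {
  check_scalar_number(setpoint_c, "setpoint_c")
  check_scalar_number(deadband_c, "deadband_c", positive = TRUE)
  structure(
    list(setpoint_c = setpoint_c, deadband_c = deadband_c),
    class = "thermostat_controller"
  )
}

#' Simulate thermostat-controlled reservoir heating
#'
#' Explicit-Euler integration of the lumped energy balance under bang-bang
#' control. The step `dt_s` must stay well below the thermal time constant
#' `m c / k` (a tenth at most) for the scheme to be stable.
#'
#' @param model A [thermal_model()].
#' @param controller A [thermostat_controller()].
#' @param t_initial_c Initial water temperature, degC.
#' @param duration_s Simulated duration, seconds (>= `dt_s`).
#' @param dt_s Integration step, seconds (> 0).
#'
#' @return A tibble of class `thermal_trace` with columns `time_s`, `temp_c`
#'   and `heater_on` (the state applied over the step starting at that
#'   sample), plus attribute `dt_s`. Supports [autoplot()].
#' @export
#' @examples
#' tr <- simulate_heating(thermal_model(), thermostat_controller(), duration_s = 1200)
#' range(tr$temp_c)
simulate_heating <- function(model, controller,
                             t_initial_c = 20, duration_s = 3600, dt_s = 1) {
  stopifnot(inherits(model, "thermal_model"), inherits(controller, "thermostat_controller"))
  check_scalar_number(dt_s, "dt_s", positive = TRUE)
  check_scalar_number(duration_s, "duration_s", positive = TRUE)
  if (duration_s < dt_s) stop_config("`duration_s` must be at least one step `dt_s`")
  mc <- model$volume_l * model$density_kg_per_l * model$specific_heat_j_per_kg_c
  k <- model$loss_coefficient_w_per_c
  if (k > 0 && dt_s >= (mc / k) / 10) {
    stop_stability(sprintf(
      "dt_s = %g s is too coarse for the thermal time constant %g s; use dt_s < %g s",
      dt_s, mc / k, (mc / k) / 10
    ))
  }
  n <- as.integer(floor(duration_s / dt_s))
  lo <- controller$setpoint_c - controller$deadband_c / 2
  hi <- controller$setpoint_c + controller$deadband_c / 2
  temps <- numeric(n + 1L)
  heater <- logical(n + 1L)
  temps[1L] <- t_initial_c
  u <- FALSE
  for (i in seq_len(n)) {
    t_cur <- temps[i]
    u <- if (t_cur < lo) TRUE else if (t_cur > hi) FALSE else u
    heater[i] <- u
    dT <- (model$heater_power_w * u - k * (t_cur - model$ambient_c)) / mc
    temps[i + 1L] <- t_cur + dT * dt_s
  }
  heater[n + 1L] <- u
  tibble::new_tibble(
    list(
      time_s = (0:n) * dt_s,
      temp_c = temps,
      heater_on = heater
    ),
    dt_s = dt_s,
    class = "thermal_trace"
  )
}

#' Steady-state temperature of a thermostat trace
#'
#' Time-average of the final `tail_fraction` of the trace, taken once the
#' controller limit cycle is established. The tail is considered converged
#' when it contains at least two heater switch events, or when it is already
#' steady (temperature range at most 0.01 degC, e.g. a heater-off trace that
#' has relaxed to ambient).
#'
#' @param trace A `thermal_trace` from [simulate_heating()].
#' @param tail_fraction Fraction of the trace to average over, in (0, 1].
#' @return Temperature in degC.
#' @export
steady_state_temperature <- function(trace, tail_fraction = 0.5) {
  if (!all(c("time_s", "temp_c", "heater_on") %in% names(trace))) {
    stop_shape("`trace` must have columns `time_s`, `temp_c`, `heater_on`")
  }
  check_scalar_number(tail_fraction, "tail_fraction", positive = TRUE)
  if (tail_fraction > 1) stop_config("`tail_fraction` must be in (0, 1]")
  n <- nrow(trace)
  if (n < 2L) stop_shape("trace too short")
  idx <- seq.int(from = n - ceiling(tail_fraction * n) + 1L, to = n)
  tail_temp <- trace$temp_c[idx]
  switches <- sum(diff(trace$heater_on[idx]) != 0)
  steady <- (max(tail_temp) - min(tail_temp)) <= 0.01
  if (switches < 2L && !steady) {
    stop_convergence(
      "no limit cycle in the trace tail (fewer than 2 thermostat switch events); simulate longer"
    )
  }
  mean(tail_temp)
}
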