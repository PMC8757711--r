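# PWM impeller-pump model, bucket-test calibration and duty scheduling.

#' Pump duty-cycle to flow model
#'
#' The impeller pump is driven by an 8-bit PWM duty (0-255 counts). The model
#' is affine above a deadband: commanded raw flow is
#' `gain * (duty - deadband_duty)` for `duty > deadband_duty`, zero otherwise.
#' The pump's actual output deviates from the command by an affine correction
#' `actual = a * raw + b` (slope `correction_slope`, intercept
#' `correction_intercept`), floored at zero; a perfectly calibrated pump has
#' `a = 1, b = 0`. Defaults (deadband 55, gain 0.03 L/min per count) span
#' 0-6 L/min, the loop's operating range.
#'
#' @param deadband_duty Duty counts below which the pump does not turn,
#'   in `[0, max_duty)`.
#' @param gain_lpm_per_count Flow gained per duty count above the deadband,
#'   L/min per count (> 0).
#' @param correction_slope,correction_intercept Affine deviation of actual
#'   from commanded flow (dimensionless slope; intercept in L/min).
#' @param max_duty Maximum duty count (8-bit PWM: 255).
#'
#' @return A list of class `pump_model`.
#' @export
pump_model <- function(deadband_duty = 55,
                       gain_lpm_per_count = 0.03,
                       correction_slope = 1,
                       correction_intercept = 0,
                       max_duty = 255) {
  check_scalar_number(deadband_duty, "deadband_duty", non_negative = TRUE)
  check_scalar_number(gain_lpm_per_count, "gain_lpm_per_count", positive = TRUE)
  check_scalar_number(correction_slope, "correction_slope")
  check_scalar_number(correction_intercept, "correction_intercept")
  check_scalar_number(max_duty, "max_duty", positive = TRUE)
  if (deadband_duty >= max_duty) {
    stop_config("`deadband_duty` must be smaller than `max_duty`")
  }
  structure(
    list(
      deadband_duty = deadband_duty,
      gain_lpm_per_count = gain_lpm_per_count,
      correction_slope = correction_slope,
      correction_intercept = correction_intercept,
      max_duty = max_duty
    ),
    class = "pump_model"
  )
}

#' Flow produced at a PWM duty
#'
#' Zero at or below the deadband; otherwise the affine-corrected commanded
#' flow, floored at zero. `duty` may be fractional (the model is continuous);
#' the hardware path through [duty_for_flow()] quantizes to integer counts.
#'
#' @param pump A [pump_model()].
#' @param duty Duty counts in `[0, max_duty]`. Vectorized.
#' @return Flow in L/min.
#' @export
flow_for_duty <- function(pump, duty) {
  stopifnot(inherits(pump, "pump_model"))
  if (any(!is.finite(duty)) || any(duty < 0) || any(duty > pump$max_duty)) {
    stop_domain(sprintf("duty must lie in [0, %g]", pump$max_duty))
  }
  raw <- pump$gain_lpm_per_count * pmax(duty - pump$deadband_duty, 0)
  corrected <- pmax(pump$correction_slope * raw + pump$correction_intercept, 0)
  ifelse(duty <= pump$deadband_duty, 0, corrected)
}

#' Maximum flow the pump can produce
#'
#' @param pump A [pump_model()].
#' @return Flow in L/min at full duty.
#' @export
pump_max_flow <- function(pump) flow_for_duty(pump, pump$max_duty)

# continuous-duty inverse of flow_for_duty (no rounding); used by the
# calibration procedure, which commands the raw setpoint directly
duty_for_flow_continuous <- function(pump, flow, correct = TRUE) {
  raw <- if (correct) {
    (flow - pump$correction_intercept) / pump$correction_slope
  } else {
    flow
  }
  pump$deadband_duty + raw / pump$gain_lpm_per_count
}

#' Integer PWM duty needed for a target flow
#'
#' Inverts [flow_for_duty()], rounds to the nearest integer count and clips
#' to `[deadband_duty, max_duty]`; a target of exactly zero maps to duty 0.
#' Round-tripping through [flow_for_duty()] is accurate to half a gain step.
#'
#' @param pump A [pump_model()].
#' @param flow Target flow in L/min (>= 0). Vectorized.
#' @return Integer duty counts.
#' @export
duty_for_flow <- function(pump, flow) {
  stopifnot(inherits(pump, "pump_model"))
  if (any(!is.finite(flow)) || any(flow < 0)) {
    stop_domain("target flow must be >= 0")
  }
  fmax <- pump_max_flow(pump)
  if (any(flow > fmax + 1e-9)) {
    stop_range(sprintf(
      "target flow %g L/min exceeds the pump maximum of %g L/min",
      max(flow), fmax
    ))
  }
  duty <- round(duty_for_flow_continuous(pump, flow))
  duty <- pmin(pmax(duty, pump$deadband_duty), pump$max_duty)
  as.integer(ifelse(flow == 0, 0, duty))
}

#' Bucket-test measurement of pump output
#'
#' Emulates the stopwatch calibration procedure: run the pump at a fixed
#' duty, time how long it takes to fill a marked volume, and report
#' `volume / time` as the measured flow. Timing error is Gaussian jitter on
#' the fill time (truncated so the time stays positive), mirroring a manual
#' stopwatch reading.
#'
#' @param pump A [pump_model()].
#' @param duty Duty counts; must produce non-zero flow.
#' @param mark_volume_l Marked fill volume in liters (> 0).
#' @param timing_sd_s Standard deviation of the timing error, seconds (>= 0).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Measured flow in L/min.
#' @export
bucket_test <- function(pump, duty, mark_volume_l = 1, timing_sd_s = 0.1, seed = 1L) {
  stopifnot(inherits(pump, "pump_model"))
  check_scalar_number(mark_volume_l, "mark_volume_l", positive = TRUE)
  check_scalar_number(timing_sd_s, "timing_sd_s", non_negative = TRUE)
  true_flow <- flow_for_duty(pump, duty)
  if (true_flow <= 0) {
    stop_domain(sprintf("no flow at this duty (%g is within the pump deadband)", duty))
  }
  fill_time_s <- 60 * mark_volume_l / true_flow
  t_s <- withr::with_seed(as.integer(seed), {
    t <- fill_time_s + rnorm(1, 0, timing_sd_s)
    while (t <= 0) t <- fill_time_s + rnorm(1, 0, timing_sd_s)
    t
  })
  60 * mark_volume_l / t_s
}

#' Fit the linear flow-correction regression
#'
#' Ordinary least squares of measured flow on set (commanded) flow over the
#' calibration trials, the "linear correlation line" implemented in the pump
#' controller. The fitted slope and intercept estimate the pump's affine
#' deviation; `r_squared = 1 - SS_res / SS_tot`.
#'
#' @param trials A data frame with columns `set_flow_lpm` and
#'   `measured_flow_lpm`, both positive; at least 2 rows spanning at least 2
#'   distinct set flows.
#'
#' @return An object of class `flow_calibration`: a list with `slope`,
#'   `intercept`, `r_squared`, the `trials` tibble and the underlying `lm`
#'   fit. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' tr <- tibble::tibble(set_flow_lpm = 3:6, measured_flow_lpm = 1.012 * (3:6) - 0.0423)
#' glance(fit_linear_calibration(tr))
fit_linear_calibration <- function(trials) {
  trials <- tibble::as_tibble(trials)
  if (!all(c("set_flow_lpm", "measured_flow_lpm") %in% names(trials))) {
    stop_shape("`trials` must have columns `set_flow_lpm` and `measured_flow_lpm`")
  }
  if (nrow(trials) < 2L) {
    stop_degenerate("calibration needs at least 2 trials")
  }
  if (any(trials$set_flow_lpm <= 0) || any(trials$measured_flow_lpm <= 0)) {
    stop_domain("calibration flows must all be > 0")
  }
  if (length(unique(trials$set_flow_lpm)) < 2L) {
    stop_degenerate("degenerate design: all trials share one set flow; need >= 2 distinct set flows")
  }
  fit <- lm(measured_flow_lpm ~ set_flow_lpm, data = trials)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((trials$measured_flow_lpm - mean(trials$measured_flow_lpm))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[["set_flow_lpm"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r_squared = 1 - ss_res / ss_tot,
      trials = trials,
      fit = fit
    ),
    class = "flow_calibration"
  )
}

#' @export
print.flow_calibration <- function(x, ...) {
  cat("<flow_calibration>\n")
  cat(sprintf(
    "  measured = %.4f * set %+.4f L/min   (r^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$trials)
  ))
  invisible(x)
}

#' Constant-flow verification run
#'
#' Replays the loop's constant-flow verification: for each setpoint the pump
#' is commanded at that raw flow (continuous duty), a simulated bucket test
#' measures the output (`trials_per_point` repeats), and the linear
#' correction regression is fitted to measured vs. set flow. With a
#' perfectly calibrated pump and no timing jitter the fit is exactly the
#' identity.
#'
#' @param pump A [pump_model()].
#' @param setpoints_lpm Set flows in L/min (default 3-6 L/min, the loop's
#'   design range); at least 2 distinct values, all within pump range.
#' @param trials_per_point Bucket-test repeats per setpoint.
#' @param timing_sd_s Stopwatch jitter passed to [bucket_test()].
#' @param mark_volume_l Marked fill volume passed to [bucket_test()].
#' @param seed Integer seed; trial `k` (in running order) uses `seed + k - 1`.
#'
#' @return A `flow_calibration` whose `trials` tibble carries one row per
#'   (setpoint, trial).
#' @export
verify_constant_flow <- function(pump,
                                 setpoints_lpm = c(3, 4, 5, 6),
                                 trials_per_point = 3L,
                                 timing_sd_s = 0.1,
                                 mark_volume_l = 1,
                                 seed = 1L) {
  stopifnot(inherits(pump, "pump_model"))
  if (length(setpoints_lpm) == 0L) stop_shape("`setpoints_lpm` must be non-empty")
  if (any(setpoints_lpm <= 0)) stop_domain("setpoints must be > 0")
  duty_cmd <- duty_for_flow_continuous(pump, setpoints_lpm, correct = FALSE)
  if (any(duty_cmd > pump$max_duty + 1e-9)) {
    stop_range(sprintf(
      "setpoint %g L/min is beyond the pump's commandable range",
      max(setpoints_lpm)
    ))
  }
  grid <- expand_trial_grid(setpoints_lpm, seq_len(trials_per_point))
  trials <- purrr::pmap_dfr(
    list(grid$set, grid$trial, seq_len(nrow(grid))),
    function(set, trial, k) {
      duty <- duty_for_flow_continuous(pump, set, correct = FALSE)
      tibble::tibble(
        set_flow_lpm = set,
        trial = trial,
        measured_flow_lpm = bucket_test(
          pump, duty,
          mark_volume_l = mark_volume_l,
          timing_sd_s = timing_sd_s,
          seed = as.integer(seed) + k - 1L
        )
      )
    }
  )
  fit_linear_calibration(trials)
}

# trial ordering is setpoint-major, trial-minor; seeds follow running order
expand_trial_grid <- function(setpoints, trials) {
  tibble::tibble(
    set = rep(setpoints, each = length(trials)),
    trial = rep(trials, times = length(setpoints))
  )
}

#' Convert a step schedule into a PWM duty schedule
#'
#' Maps each step's flow through [duty_for_flow()]; durations are preserved.
#' This is the table the pump controller iterates over each cycle.
#'
#' @param pump A [pump_model()].
#' @param schedule A [step_schedule()].
#' @return A tibble with columns `duration_s` and `duty`.
#' @export
schedule_duties <- function(pump, schedule) {
  stopifnot(inherits(pump, "pump_model"), inherits(schedule, "step_schedule"))
  tibble::tibble(
    duration_s = schedule$duration_s,
    duty = duty_for_flow(pump, schedule$flow_lpm)
  )
}
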