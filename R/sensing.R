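# Hall-effect turbine flow-sensor model: pulse counting, calibration and
# multi-cycle averaging.

#' Hall-effect turbine flow sensor
#'
#' An in-line turbine whose spins emit pulses proportional to throughput
#' volume. The default 396 pulses/L corresponds to the YF-B2's nominal
#' ~6.6 Hz per L/min; in practice the factor is obtained from
#' [calibrate_correction_factor()].
#'
#' @param pulses_per_liter Pulses emitted per liter of throughput (> 0).
#' @param window_s Default counting window in seconds (> 0).
#' @param count_jitter_sd Standard deviation of Gaussian noise on the pulse
#'   count per window, in pulses (>= 0).
#'
#' @return A list of class `turbine_sensor`.
#' @export
turbine_sensor <- function(pulses_per_liter = 396,
                           window_s = 10,
                           count_jitter_sd = 2) {
  check_scalar_number(pulses_per_liter, "pulses_per_liter", positive = TRUE)
  check_scalar_number(window_s, "window_s", positive = TRUE)
  check_scalar_number(count_jitter_sd, "count_jitter_sd", non_negative = TRUE)
  structure(
    list(
      pulses_per_liter = pulses_per_liter,
      window_s = window_s,
      count_jitter_sd = count_jitter_sd
    ),
    class = "turbine_sensor"
  )
}

#' Construct a sensor recording
#'
#' One counting-window observation: the window length, the (non-negative
#' integer) pulse count, and optionally the true mean flow through the
#' window, kept for calibration fixtures.
#'
#' @param window_s Counting window, seconds (> 0).
#' @param pulse_count Non-negative integer pulse count.
#' @param true_flow_lpm Optional true mean flow over the window, L/min.
#' @return A one-row tibble with columns `window_s`, `pulse_count`,
#'   `true_flow_lpm`.
#' @export
sensor_recording <- function(window_s, pulse_count, true_flow_lpm = NA_real_) {
  check_scalar_number(window_s, "window_s", positive = TRUE)
  if (!is.numeric(pulse_count) || length(pulse_count) != 1L ||
    pulse_count < 0 || pulse_count != round(pulse_count)) {
    stop_domain("`pulse_count` must be a single non-negative integer")
  }
  tibble::tibble(
    window_s = window_s,
    pulse_count = as.integer(pulse_count),
    true_flow_lpm = true_flow_lpm
  )
}

#' Simulate turbine pulse counts over a window
#'
#' Integrates the (periodically extended) flow signal over the window to get
#' throughput volume, scales by the sensor's pulses-per-liter factor, adds
#' Gaussian count jitter, rounds and floors at zero.
#'
#' @param sensor A [turbine_sensor()].
#' @param wave A [flow_waveform()] or [step_schedule()] describing the flow.
#' @param window_s Counting window in seconds (default: the sensor's).
#' @param seed Integer seed; the count is reproducible given the seed.
#' @return A [sensor_recording()] whose `true_flow_lpm` holds the exact mean
#'   flow over the window.
#' @export
#' @examples
#' s <- turbine_sensor(396, count_jitter_sd = 0)
#' simulate_pulse_counts(s, constant_waveform(3), window_s = 10, seed = 1)
simulate_pulse_counts <- function(sensor, wave, window_s = sensor$window_s, seed = 1L) {
  stopifnot(inherits(sensor, "turbine_sensor"))
  check_scalar_number(window_s, "window_s", positive = TRUE)
  volume_l <- integrate_flow_time(wave, window_s) / 60
  count <- withr::with_seed(as.integer(seed), {
    max(0, round(sensor$pulses_per_liter * volume_l + rnorm(1, 0, sensor$count_jitter_sd)))
  })
  sensor_recording(window_s, count, true_flow_lpm = 60 * volume_l / window_s)
}

#' Convert a pulse-count recording to flow
#'
#' `flow = 60 * (count / window) / pulses_per_liter` L/min — the spins-to-
#' L/min correction applied in the loop's display code.
#'
#' @param sensor A [turbine_sensor()].
#' @param recording A recording tibble (as from [simulate_pulse_counts()]);
#'   may hold several rows.
#' @return Flow in L/min, one value per recording row.
#' @export
flow_from_counts <- function(sensor, recording) {
  stopifnot(inherits(sensor, "turbine_sensor"))
  if (!all(c("window_s", "pulse_count") %in% names(recording))) {
    stop_shape("`recording` must have columns `window_s` and `pulse_count`")
  }
  if (any(recording$window_s <= 0)) {
    stop_domain("recording window must be > 0")
  }
  60 * (recording$pulse_count / recording$window_s) / sensor$pulses_per_liter
}

#' Calibrate the sensor's pulses-per-liter correction factor
#'
#' For each recording with a known true flow, the implied factor is
#' `count / (true_flow / 60 * window)`; the calibrated factor is the mean
#' over recordings (the loop's procedure averaged 10 windows per flow rate).
#'
#' @param recordings A tibble with columns `window_s`, `pulse_count`,
#'   `true_flow_lpm` (all rows with known, positive true flow).
#' @return The calibrated pulses-per-liter factor.
#' @export
calibrate_correction_factor <- function(recordings) {
  if (is.null(recordings) || nrow(recordings) == 0L) {
    stop_shape("need at least one recording to calibrate")
  }
  if (!all(c("window_s", "pulse_count", "true_flow_lpm") %in% names(recordings))) {
    stop_shape("`recordings` must have columns `window_s`, `pulse_count`, `true_flow_lpm`")
  }
  if (any(!is.finite(recordings$true_flow_lpm)) || any(recordings$true_flow_lpm <= 0)) {
    stop_domain("every recording must carry a true flow > 0")
  }
  factors <- recordings$pulse_count /
    (recordings$true_flow_lpm / 60 * recordings$window_s)
  mean(factors)
}

#' Sensor-measured average flow over repeated multi-cycle windows
#'
#' Replays the loop's pulsatile validation: each trial counts pulses over a
#' window of `n_cycles` full cycles of the running schedule and converts the
#' count to an average flow; the trials' mean and sample SD are reported.
#' With a noiseless sensor the mean equals the schedule's time-weighted
#' average up to one pulse quantum.
#'
#' @param schedule A [step_schedule()] (or [flow_waveform()]) the pump runs.
#' @param sensor A [turbine_sensor()].
#' @param n_cycles Cycles per counting window (>= 1).
#' @param n_trials Number of repeated readings (>= 1).
#' @param seed Integer seed; trial `i` uses `seed + i - 1`.
#'
#' @return An object of class `pulsatile_flow_measurement`: a list with
#'   `mean_lpm`, `sd_lpm`, `n_trials`, `degenerate_sd` (`TRUE` when a single
#'   trial makes the SD undefined; it is then reported as 0), and the
#'   per-trial `trials` tibble. Supports [tidy()] and [glance()].
#' @export
measure_average_flow <- function(schedule, sensor,
                                 n_cycles = 10L, n_trials = 3L, seed = 1L) {
  stopifnot(inherits(sensor, "turbine_sensor"))
  if (!is.numeric(n_cycles) || n_cycles < 1) stop_config("`n_cycles` must be >= 1")
  if (!is.numeric(n_trials) || n_trials < 1) stop_config("`n_trials` must be >= 1")
  period <- wave_period(schedule)
  window_s <- n_cycles * period
  trials <- purrr::map_dfr(seq_len(n_trials), function(i) {
    rec <- simulate_pulse_counts(sensor, schedule,
      window_s = window_s,
      seed = as.integer(seed) + i - 1L
    )
    tibble::tibble(
      trial = i,
      window_s = rec$window_s,
      pulse_count = rec$pulse_count,
      flow_lpm = flow_from_counts(sensor, rec)
    )
  })
  degenerate <- n_trials < 2
  structure(
    list(
      mean_lpm = mean(trials$flow_lpm),
      sd_lpm = if (degenerate) 0 else sd(trials$flow_lpm),
      n_trials = as.integer(n_trials),
      degenerate_sd = degenerate,
      trials = trials
    ),
    class = "pulsatile_flow_measurement"
  )
}

#' @export
print.pulsatile_flow_measurement <- function(x, ...) {
  cat("<pulsatile_flow_measurement>\n")
  cat(sprintf(
    "  measured average flow: %.2f +/- %.2f L/min over %d trial%s%s\n",
    x$mean_lpm, x$sd_lpm, x$n_trials, if (x$n_trials == 1) "" else "s",
    if (x$degenerate_sd) " (single trial: SD undefined, reported as 0)" else ""
  ))
  invisible(x)
}
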