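# Pulsatile venous waveform synthesis and step-schedule discretization.
#
# A flow_waveform is one period of a flow signal on a uniform time grid:
# a tibble with columns time_s, flow_lpm and a period_s attribute. It is the
# central exchange type between the waveform generator, the split-tube
# combiner and the pump/sensor simulators.

#' Construct a single-period flow waveform
#'
#' A waveform is one cycle of a flow-rate signal sampled on a uniform grid
#' `times` in `[0, period)`. Between samples the signal is treated as
#' piecewise linear with periodic closure (the sample at `period` equals the
#' first sample).
#'
#' @param times Sample times in seconds, uniformly spaced, starting in
#'   `[0, period)`. At least 8 samples.
#' @param flows Flow at each sample, L/min.
#' @param period Cycle period in seconds.
#'
#' @return A tibble of class `flow_waveform` with columns `time_s`,
#'   `flow_lpm` and attribute `period_s`.
#' @export
#' @examples
#' w <- flow_waveform(seq(0, 0.875, by = 0.125), rep(3, 8), period = 1)
#' time_weighted_average(w)
flow_waveform <- function(times, flows, period) {
  check_scalar_number(period, "period", positive = TRUE)
  if (length(times) != length(flows)) {
    stop_shape("`times` and `flows` must have the same length")
  }
  n <- length(times)
  if (n < 8L) {
    stop_shape(sprintf("a flow waveform needs at least 8 samples (got %d)", n))
  }
  if (any(!is.finite(times)) || any(!is.finite(flows))) {
    stop_domain("waveform samples must be finite")
  }
  if (any(times < 0) || any(times >= period)) {
    stop_shape("sample times must lie in [0, period)")
  }
  dt <- diff(times)
  if (max(abs(dt - period / n)) > 1e-9) {
    stop_shape("sample times must be uniformly spaced over the period (within 1e-9 s)")
  }
  tibble::new_tibble(
    list(time_s = as.numeric(times), flow_lpm = as.numeric(flows)),
    period_s = period,
    class = "flow_waveform"
  )
}

#' Waveform or schedule period
#'
#' @param x A `flow_waveform` or `step_schedule`.
#' @return Period in seconds.
#' @export
wave_period <- function(x) {
  p <- attr(x, "period_s")
  if (is.null(p)) stop_shape("object has no `period_s` attribute")
  p
}

#' Construct a timed step schedule
#'
#' A step schedule partitions one cycle into contiguous steps of constant
#' flow; it is the form the pump controller actually runs (a timed stepping
#' function adjusting the PWM duty).
#'
#' @param durations Step durations in seconds, all > 0; must sum to `period`.
#' @param flows Constant flow per step, L/min, all >= 0 (the impeller pump is
#'   unidirectional).
#' @param period Cycle period in seconds. Defaults to the sum of durations.
#'
#' @return A tibble of class `step_schedule` with columns `duration_s`,
#'   `flow_lpm` and attribute `period_s`.
#' @export
step_schedule <- function(durations, flows, period = sum(durations)) {
  check_scalar_number(period, "period", positive = TRUE)
  if (length(durations) == 0L) stop_shape("a step schedule needs at least one step")
  if (length(durations) != length(flows)) {
    stop_shape("`durations` and `flows` must have the same length")
  }
  if (any(durations <= 0)) stop_domain("step durations must all be > 0")
  if (any(flows < 0)) stop_domain("step flows must all be >= 0")
  if (abs(sum(durations) - period) > 1e-9) {
    stop_shape("step durations must sum to the period (within 1e-9 s)")
  }
  tibble::new_tibble(
    list(duration_s = as.numeric(durations), flow_lpm = as.numeric(flows)),
    period_s = period,
    class = "step_schedule"
  )
}

#' Parameters of the parametric venous waveform family
#'
#' The waveform family is a biphasic venous pattern: a baseline modulated by
#' a systolic lobe, a diastolic lobe and a subtracted atrial-reversal dip,
#' each a raised-cosine bump. Lobe centers and widths are expressed as
#' fractions of the period so the shape is heart-rate invariant. After shaping,
#' the waveform is rescaled multiplicatively so its cycle mean is exactly the
#' branch share of `mean_total_lpm` (`svc_fraction` for the SVC branch,
#' `1 - svc_fraction` for the IVC).
#'
#' Defaults describe the loop's resting operating point: 60 bpm, total venous
#' return 3.10 L/min with a physiological SVC:IVC split of 1:2, systolic lobe
#' (amplitude 0.8, center 0.25, width 0.25), diastolic lobe (0.5, 0.65, 0.25)
#' and atrial-reversal dip (0.3, 0.95, 0.15).
#'
#' @param heart_rate_bpm Heart rate, beats per minute (> 0); period is
#'   `60 / heart_rate_bpm` seconds.
#' @param mean_total_lpm Target cycle-mean of SVC + IVC flow, L/min (> 0).
#' @param svc_fraction Fraction of the mean carried by the SVC, in (0, 1).
#' @param amp_systolic,amp_diastolic,amp_reversal Lobe amplitudes (>= 0),
#'   dimensionless multiples of the baseline.
#' @param center_systolic,center_diastolic,center_reversal Lobe centers as
#'   fractions of the period, in (0, 1].
#' @param width_systolic,width_diastolic,width_reversal Lobe full widths as
#'   fractions of the period, in (0, 1].
#'
#' @return A list of class `venous_waveform_params`.
#' @export
venous_waveform_params <- function(heart_rate_bpm = 60,
                                   mean_total_lpm = 3.10,
                                   svc_fraction = 1 / 3,
                                   amp_systolic = 0.8,
                                   center_systolic = 0.25,
                                   width_systolic = 0.25,
                                   amp_diastolic = 0.5,
                                   center_diastolic = 0.65,
                                   width_diastolic = 0.25,
                                   amp_reversal = 0.3,
                                   center_reversal = 0.95,
                                   width_reversal = 0.15) {
  check_scalar_number(heart_rate_bpm, "heart_rate_bpm", positive = TRUE)
  check_scalar_number(mean_total_lpm, "mean_total_lpm", positive = TRUE)
  check_scalar_number(svc_fraction, "svc_fraction")
  if (svc_fraction <= 0 || svc_fraction >= 1) {
    stop_config(sprintf("`svc_fraction` must lie in (0, 1) (got %g)", svc_fraction))
  }
  for (a in c("amp_systolic", "amp_diastolic", "amp_reversal")) {
    check_scalar_number(get(a), a, non_negative = TRUE)
  }
  for (f in c(
    "center_systolic", "width_systolic", "center_diastolic",
    "width_diastolic", "center_reversal", "width_reversal"
  )) {
    v <- get(f)
    check_scalar_number(v, f)
    if (v <= 0 || v > 1) {
      stop_config(sprintf("`%s` must lie in (0, 1] as a fraction of the period (got %g)", f, v))
    }
  }
  structure(
    list(
      heart_rate_bpm = heart_rate_bpm,
      mean_total_lpm = mean_total_lpm,
      svc_fraction = svc_fraction,
      amp_systolic = amp_systolic,
      center_systolic = center_systolic,
      width_systolic = width_systolic,
      amp_diastolic = amp_diastolic,
      center_diastolic = center_diastolic,
      width_diastolic = width_diastolic,
      amp_reversal = amp_reversal,
      center_reversal = center_reversal,
      width_reversal = width_reversal
    ),
    class = "venous_waveform_params"
  )
}

# periodic raised-cosine lobe on phase u in [0, 1):
# 1/2 (1 + cos(2 pi d / w)) for wrapped distance |d| <= w/2, else 0
raised_cosine_lobe <- function(u, center, width) {
  d <- u - center
  d <- d - round(d) # wrap to [-0.5, 0.5)
  out <- numeric(length(u))
  inside <- abs(d) <= width / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * d[inside] / width))
  out
}

#' Synthesize a pulsatile vena-cava flow waveform
#'
#' Evaluates the biphasic venous shape family of [venous_waveform_params()]
#' on a uniform grid and rescales it so that the cycle mean equals the branch
#' target: `svc_fraction * mean_total_lpm` for the SVC,
#' `(1 - svc_fraction) * mean_total_lpm` for the IVC.
#'
#' @param params A [venous_waveform_params()] object.
#' @param branch `"svc"` or `"ivc"`.
#' @param n_samples Samples per cycle (>= 8).
#'
#' @return A [flow_waveform()].
#' @export
#' @examples
#' svc <- venous_waveform(venous_waveform_params(), "svc")
#' time_weighted_average(svc) # = 3.10 / 3
venous_waveform <- function(params = venous_waveform_params(),
                            branch = c("svc", "ivc"),
                            n_samples = 256L) {
  stopifnot(inherits(params, "venous_waveform_params"))
  branch <- match.arg(tolower(branch), c("svc", "ivc"))
  if (!is.numeric(n_samples) || n_samples < 8) {
    stop_config("`n_samples` must be at least 8")
  }
  n <- as.integer(n_samples)
  period <- 60 / params$heart_rate_bpm
  times <- (seq_len(n) - 1L) * period / n
  u <- times / period
  shape <- 1 +
    params$amp_systolic * raised_cosine_lobe(u, params$center_systolic, params$width_systolic) +
    params$amp_diastolic * raised_cosine_lobe(u, params$center_diastolic, params$width_diastolic) -
    params$amp_reversal * raised_cosine_lobe(u, params$center_reversal, params$width_reversal)
  m <- mean(shape)
  if (m <= 0) {
    stop_config("waveform parameters produce a non-positive cycle mean; reduce the reversal amplitude")
  }
  target <- if (branch == "svc") {
    params$svc_fraction * params$mean_total_lpm
  } else {
    (1 - params$svc_fraction) * params$mean_total_lpm
  }
  flow_waveform(times, target * shape / m, period)
}

#' Constant flow waveform
#'
#' The loop's constant-flow operating mode (nominally 3-6 L/min) expressed as
#' a waveform, so constant and pulsatile runs share one code path.
#'
#' @param flow Flow in L/min (>= 0).
#' @param period Cycle period in seconds.
#' @param n_samples Samples per cycle (>= 8).
#'
#' @return A [flow_waveform()].
#' @export
constant_waveform <- function(flow, period = 1, n_samples = 16L) {
  check_scalar_number(flow, "flow", non_negative = TRUE)
  n <- as.integer(n_samples)
  times <- (seq_len(n) - 1L) * period / n
  flow_waveform(times, rep(flow, n), period)
}

#' Time-weighted average flow over one cycle
#'
#' The loop's pulsatile-flow validation statistic: the integral of flow over
#' one period divided by the period. For a sampled waveform this is the
#' trapezoidal mean with periodic closure, which on a uniform grid reduces to
#' the arithmetic mean of the samples; for a step schedule it is the exact
#' duration-weighted mean.
#'
#' @param x A [flow_waveform()] or [step_schedule()].
#' @param ... Unused.
#' @return Flow in L/min.
#' @export
time_weighted_average <- function(x, ...) UseMethod("time_weighted_average")

#' @export
time_weighted_average.flow_waveform <- function(x, ...) {
  if (nrow(x) == 0L) stop_shape("empty waveform")
  mean(x$flow_lpm)
}

#' @export
time_weighted_average.step_schedule <- function(x, ...) {
  if (nrow(x) == 0L) stop_shape("empty step schedule")
  sum(x$flow_lpm * x$duration_s) / wave_period(x)
}

#' @export
time_weighted_average.default <- function(x, ...) {
  stop_shape("`x` must be a flow_waveform or step_schedule")
}

# integral of the piecewise-linear periodic extension of `wave` over
# [0, t_end], in L/min * s; divide by 60 for liters
integrate_flow_time <- function(wave, t_end) {
  period <- wave_period(wave)
  if (inherits(wave, "step_schedule")) {
    bounds <- cumsum(c(0, wave$duration_s))
    one_cycle <- sum(wave$flow_lpm * wave$duration_s)
    partial <- function(t) {
      full <- pmin(pmax(t - head(bounds, -1), 0), wave$duration_s)
      sum(wave$flow_lpm * full)
    }
  } else {
    tt <- c(wave$time_s, period)
    ff <- c(wave$flow_lpm, wave$flow_lpm[1])
    one_cycle <- sum(diff(tt) * (head(ff, -1) + tail(ff, -1)) / 2)
    fun <- approxfun(tt, ff)
    partial <- function(t) {
      if (t <= 0) {
        return(0)
      }
      pts <- sort(unique(c(tt[tt <= t], t)))
      vals <- fun(pts)
      sum(diff(pts) * (head(vals, -1) + tail(vals, -1)) / 2)
    }
  }
  k <- floor(t_end / period)
  rem <- t_end - k * period
  k * one_cycle + partial(rem)
}

#' Discretize a waveform into a timed step schedule
#'
#' Partitions the period into `n_steps` equal steps; each step's flow is the
#' exact mean of the piecewise-linear waveform over that sub-interval,
#' clipped below at zero (the pump cannot reverse). For non-negative
#' waveforms the schedule's time-weighted average equals the waveform's.
#'
#' @param wave A [flow_waveform()].
#' @param n_steps Number of equal-duration steps per cycle (>= 2).
#'
#' @return A [step_schedule()].
#' @export
discretize_to_steps <- function(wave, n_steps = 20L) {
  stopifnot(inherits(wave, "flow_waveform"))
  if (!is.numeric(n_steps) || n_steps < 2) {
    stop_config("`n_steps` must be at least 2")
  }
  n <- as.integer(n_steps)
  period <- wave_period(wave)
  tt <- c(wave$time_s, period)
  ff <- c(wave$flow_lpm, wave$flow_lpm[1])
  fun <- approxfun(tt, ff)
  bounds <- seq(0, period, length.out = n + 1L)
  means <- purrr::map_dbl(seq_len(n), function(k) {
    lo <- bounds[k]
    hi <- bounds[k + 1L]
    pts <- sort(unique(c(lo, tt[tt > lo & tt < hi], hi)))
    vals <- fun(pts)
    sum(diff(pts) * (head(vals, -1) + tail(vals, -1)) / 2) / (hi - lo)
  })
  step_schedule(rep(period / n, n), pmax(means, 0), period = period)
}

#' Read / write a waveform as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with header `time_s,flow_lpm`,
#' one row per sample, `.` as the decimal separator.
#'
#' @param path File path.
#' @param period Cycle period in seconds; if `NULL`, inferred from the
#'   uniform grid as `n * dt`.
#' @return `read_waveform_csv()` returns a [flow_waveform()];
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
read_waveform_csv <- function(path, period = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    flow_lpm = readr::col_double()
  ))
  if (!all(c("time_s", "flow_lpm") %in% names(df))) {
    stop_shape("waveform CSV must have columns `time_s` and `flow_lpm`")
  }
  if (is.null(period)) {
    dt <- diff(df$time_s)
    if (length(dt) < 1L) stop_shape("waveform CSV needs at least 2 samples")
    period <- nrow(df) * mean(dt)
  }
  flow_waveform(df$time_s, df$flow_lpm, period)
}

#' @rdname read_waveform_csv
#' @param wave A [flow_waveform()].
#' @export
write_waveform_csv <- function(wave, path) {
  stopifnot(inherits(wave, "flow_waveform"))
  readr::write_csv(tibble::tibble(time_s = wave$time_s, flow_lpm = wave$flow_lpm), path)
  invisible(path)
}
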