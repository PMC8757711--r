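# broom-style tidiers for fitted/measured objects.

#' Tidy a constant-flow calibration fit
#'
#' @param x A `flow_calibration` from [fit_linear_calibration()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy flow_calibration
#' @export
tidy.flow_calibration <- function(x, ...) {
  # a noiseless calibration is an exact fit; summary()'s perfect-fit
  # warning is expected there, not actionable
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p.value = co[, "Pr(>|t|)"]
  )
}

#' Glance at a constant-flow calibration fit
#'
#' @param x A `flow_calibration`.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r.squared`, `sigma`,
#'   `nobs`.
#' @method glance flow_calibration
#' @export
glance.flow_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    sigma = suppressWarnings(summary(x$fit))$sigma,
    nobs = nrow(x$trials)
  )
}

#' Tidy a pulsatile flow measurement
#'
#' @param x A `pulsatile_flow_measurement` from [measure_average_flow()].
#' @param ... Unused.
#' @return The per-trial tibble: `trial`, `window_s`, `pulse_count`,
#'   `flow_lpm`.
#' @method tidy pulsatile_flow_measurement
#' @export
tidy.pulsatile_flow_measurement <- function(x, ...) x$trials

#' Glance at a pulsatile flow measurement
#'
#' @param x A `pulsatile_flow_measurement`.
#' @param ... Unused.
#' @return A one-row tibble: `mean_lpm`, `sd_lpm`, `n_trials`,
#'   `degenerate_sd`.
#' @method glance pulsatile_flow_measurement
#' @export
glance.pulsatile_flow_measurement <- function(x, ...) {
  tibble::tibble(
    mean_lpm = x$mean_lpm,
    sd_lpm = x$sd_lpm,
    n_trials = x$n_trials,
    degenerate_sd = x$degenerate_sd
  )
}
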