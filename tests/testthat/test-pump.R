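# Pump model, bucket-test calibration and duty scheduling.

test_that("duty-to-flow map has a deadband and an affine correction", {
  pump <- pump_model(deadband_duty = 55, gain_lpm_per_count = 0.03)
  expect_equal(flow_for_duty(pump, 55), 0)
  expect_equal(flow_for_duty(pump, 0), 0)
  expect_equal(flow_for_duty(pump, 255), 6.0, tolerance = 1e-12)
  corrected <- pump_model(correction_slope = 1.012, correction_intercept = -0.0423)
  # raw 3.0 L/min sits at duty 155; corrected output is 1.012*3 - 0.0423
  expect_equal(flow_for_duty(corrected, 155), 1.012 * 3 - 0.0423, tolerance = 1e-12)
  expect_equal(round(flow_for_duty(corrected, 155), 4), 2.9937)
  expect_error(flow_for_duty(pump, 300), class = "venaloop_domain_error")
  expect_error(flow_for_duty(pump, -1), class = "venaloop_domain_error")
})

test_that("duty_for_flow inverts the map within one duty count", {
  pump <- pump_model()
  expect_identical(duty_for_flow(pump, 0), 0L)
  expect_identical(duty_for_flow(pump, 6.0), 255L)
  expect_error(duty_for_flow(pump, 7), class = "venaloop_range_error")
  expect_error(duty_for_flow(pump, -1), class = "venaloop_domain_error")
  # round trip within gain/2 for reachable flows
  flows <- seq(0.1, 6, by = 0.37)
  back <- flow_for_duty(pump, duty_for_flow(pump, flows))
  expect_true(all(abs(back - flows) <= pump$gain_lpm_per_count / 2 + 1e-12))
  # with an affine correction the round trip stays within a*gain/2
  corr <- pump_model(correction_slope = 1.012, correction_intercept = -0.0423)
  flows <- seq(0.5, 5.5, by = 0.41)
  back <- flow_for_duty(corr, duty_for_flow(corr, flows))
  expect_true(all(abs(back - flows) <= 1.012 * corr$gain_lpm_per_count / 2 + 1e-12))
})

test_that("bucket test is a noiseless oracle at zero timing jitter", {
  pump <- pump_model()
  duty <- duty_for_flow(pump, 3)
  expect_equal(bucket_test(pump, duty, 1, timing_sd_s = 0, seed = 1), 3.0, tolerance = 1e-12)
  expect_error(bucket_test(pump, 10, seed = 1), class = "venaloop_domain_error")
})

test_that("bucket test is seed-reproducible and varies across seeds", {
  pump <- pump_model()
  a <- bucket_test(pump, 200, timing_sd_s = 0.5, seed = 42)
  b <- bucket_test(pump, 200, timing_sd_s = 0.5, seed = 42)
  c <- bucket_test(pump, 200, timing_sd_s = 0.5, seed = 4242)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("OLS calibration recovers exact lines", {
  x <- c(3, 4, 5, 6)
  on_identity <- tibble::tibble(set_flow_lpm = x, measured_flow_lpm = x)
  fit <- fit_linear_calibration(on_identity)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # points constructed exactly on the bench-reported line
  on_line <- tibble::tibble(set_flow_lpm = x, measured_flow_lpm = 1.012 * x - 0.0423)
  fit <- fit_linear_calibration(on_line)
  expect_equal(fit$slope, 1.012, tolerance = 1e-9)
  expect_equal(fit$intercept, -0.0423, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # two points always give r^2 = 1
  two <- tibble::tibble(set_flow_lpm = c(3, 6), measured_flow_lpm = c(2.9, 6.2))
  expect_equal(fit_linear_calibration(two)$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate calibration designs are rejected", {
  same_x <- tibble::tibble(set_flow_lpm = c(3, 3, 3), measured_flow_lpm = c(3, 3.1, 2.9))
  expect_error(fit_linear_calibration(same_x), class = "venaloop_degenerate_error")
  expect_error(
    fit_linear_calibration(tibble::tibble(set_flow_lpm = 3, measured_flow_lpm = 3)),
    class = "venaloop_degenerate_error"
  )
  expect_error(
    fit_linear_calibration(tibble::tibble(set_flow_lpm = c(-1, 2), measured_flow_lpm = c(1, 2))),
    class = "venaloop_domain_error"
  )
})

test_that("calibration tidiers expose the regression summary", {
  x <- c(3, 4, 5, 6)
  fit <- fit_linear_calibration(
    tibble::tibble(set_flow_lpm = x, measured_flow_lpm = 1.012 * x - 0.0423)
  )
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(unname(td$estimate[td$term == "set_flow_lpm"]), 1.012, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$slope, 1.012, tolerance = 1e-9)
  expect_equal(gl$nobs, 4L)
})

test_that("noiseless constant-flow verification recovers the pump's (a, b) exactly", {
  # identity pump: identity fit
  fit <- verify_constant_flow(pump_model(), timing_sd_s = 0, seed = 1)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # miscalibrated pump: the fit recovers the deviation
  pump <- pump_model(correction_slope = 1.012, correction_intercept = -0.0423)
  fit <- verify_constant_flow(pump, timing_sd_s = 0, seed = 1)
  expect_equal(fit$slope, 1.012, tolerance = 1e-9)
  expect_equal(fit$intercept, -0.0423, tolerance = 1e-9)
})

test_that("calibration estimates tighten with more trials per point", {
  pump <- pump_model(correction_slope = 1.012, correction_intercept = -0.0423)
  err <- function(trials_per_point) {
    errs <- sapply(1:20, function(s) {
      fit <- verify_constant_flow(pump,
        trials_per_point = trials_per_point,
        timing_sd_s = 0.3, seed = 1000 * s
      )
      abs(fit$slope - 1.012)
    })
    mean(errs)
  }
  expect_lt(err(30), err(3))
})

test_that("noisy verification slope stays near unity and is seed-stable", {
  fit1 <- verify_constant_flow(pump_model(), timing_sd_s = 0.1, seed = 42)
  fit2 <- verify_constant_flow(pump_model(), timing_sd_s = 0.1, seed = 42)
  expect_identical(fit1$trials, fit2$trials)
  expect_true(fit1$slope > 0.95 && fit1$slope < 1.05)
  expect_error(
    verify_constant_flow(pump_model(), setpoints_lpm = 3, timing_sd_s = 0),
    class = "venaloop_degenerate_error"
  )
  expect_error(
    verify_constant_flow(pump_model(), setpoints_lpm = c(3, 9)),
    class = "venaloop_range_error"
  )
})

test_that("schedule duties preserve durations and reconstruct the flow within gain/2", {
  pump <- pump_model()
  sch <- discretize_to_steps(default_inflow(), 20)
  duties <- schedule_duties(pump, sch)
  expect_equal(duties$duration_s, sch$duration_s)
  reconstructed <- step_schedule(
    duties$duration_s,
    flow_for_duty(pump, duties$duty),
    period = wave_period(sch)
  )
  expect_lte(
    abs(time_weighted_average(reconstructed) - time_weighted_average(sch)),
    pump$gain_lpm_per_count / 2
  )
  # constant schedule maps to a constant duty
  const <- step_schedule(rep(0.25, 4), rep(3, 4))
  expect_equal(unique(schedule_duties(pump, const)$duty), duty_for_flow(pump, 3))
  # all-zero schedule maps to zero duty
  zeros <- step_schedule(rep(0.25, 4), rep(0, 4))
  expect_equal(unique(schedule_duties(pump, zeros)$duty), 0L)
})
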