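# Venous waveform synthesis, time-weighted averaging and step discretization.

test_that("waveform constructor enforces grid invariants", {
  expect_error(flow_waveform(c(0, 0.25, 0.5), c(1, 1, 1), 1), class = "venaloop_shape_error")
  expect_error(
    flow_waveform(c(0, 0.1, 0.2, 0.35, 0.4, 0.5, 0.6, 0.7), rep(1, 8), 0.8),
    class = "venaloop_shape_error"
  )
  expect_error(flow_waveform(seq(0, 0.875, 0.125), rep(1, 8), -1), class = "venaloop_domain_error")
  w <- flow_waveform(seq(0, 0.875, 0.125), 1:8, 1)
  expect_s3_class(w, "flow_waveform")
  expect_equal(wave_period(w), 1)
})

test_that("venous waveform hits its branch mean exactly", {
  p <- venous_waveform_params()
  svc <- venous_waveform(p, "svc")
  ivc <- venous_waveform(p, "ivc")
  expect_equal(time_weighted_average(svc), 3.10 / 3, tolerance = 1e-12)
  expect_equal(time_weighted_average(ivc), 2 * 3.10 / 3, tolerance = 1e-12)
  expect_equal(
    time_weighted_average(svc) + time_weighted_average(ivc),
    3.10,
    tolerance = 1e-12
  )
})

test_that("all-zero lobe amplitudes give a constant waveform at the branch mean", {
  p <- venous_waveform_params(amp_systolic = 0, amp_diastolic = 0, amp_reversal = 0)
  svc <- venous_waveform(p, "svc", 64)
  expect_equal(svc$flow_lpm, rep(3.10 / 3, 64), tolerance = 1e-12)
})

test_that("rescaling invariant holds for randomized lobe parameters", {
  set.seed(202)
  for (i in 1:10) {
    p <- venous_waveform_params(
      heart_rate_bpm = runif(1, 40, 120),
      mean_total_lpm = runif(1, 1, 8),
      svc_fraction = runif(1, 0.2, 0.8),
      amp_systolic = runif(1, 0, 1.5),
      center_systolic = runif(1, 0.05, 1),
      width_systolic = runif(1, 0.05, 0.5),
      amp_diastolic = runif(1, 0, 1),
      center_diastolic = runif(1, 0.05, 1),
      width_diastolic = runif(1, 0.05, 0.5),
      amp_reversal = runif(1, 0, 0.5),
      center_reversal = runif(1, 0.05, 1),
      width_reversal = runif(1, 0.05, 0.3)
    )
    target <- p$svc_fraction * p$mean_total_lpm
    expect_equal(
      time_weighted_average(venous_waveform(p, "svc", 128)),
      target,
      tolerance = 1e-9
    )
  }
})

test_that("excessive reversal amplitude is a configuration error", {
  p <- venous_waveform_params(
    amp_systolic = 0, amp_diastolic = 0,
    amp_reversal = 3, center_reversal = 0.5, width_reversal = 1
  )
  expect_error(venous_waveform(p, "svc"), class = "venaloop_config_error")
})

test_that("TWA is the trapezoidal cycle mean and is linear", {
  expect_equal(time_weighted_average(constant_waveform(3, 1, 16)), 3.0)
  n <- 64
  t <- (0:(n - 1)) / n
  sine <- flow_waveform(t, 3 + sin(2 * pi * t), 1)
  expect_equal(time_weighted_average(sine), 3.0, tolerance = 1e-12)
  # linearity on a shared grid
  set.seed(5)
  w1 <- random_waveform(n)
  w2 <- random_waveform(n)
  combo <- flow_waveform(w1$time_s, 2.5 * w1$flow_lpm - 0.5 * w2$flow_lpm, 1)
  expect_equal(
    time_weighted_average(combo),
    2.5 * time_weighted_average(w1) - 0.5 * time_weighted_average(w2),
    tolerance = 1e-12
  )
})

test_that("doubling heart rate halves the period but leaves TWA unchanged", {
  p1 <- venous_waveform_params(heart_rate_bpm = 60)
  p2 <- venous_waveform_params(heart_rate_bpm = 120)
  w1 <- venous_waveform(p1, "ivc")
  w2 <- venous_waveform(p2, "ivc")
  expect_equal(wave_period(w2), wave_period(w1) / 2)
  expect_equal(time_weighted_average(w1), time_weighted_average(w2), tolerance = 1e-12)
})

test_that("step discretization preserves TWA for non-negative waveforms", {
  w <- constant_waveform(4.2, 1, 16)
  sch <- discretize_to_steps(w, 7)
  expect_equal(sch$flow_lpm, rep(4.2, 7), tolerance = 1e-12)
  expect_equal(time_weighted_average(sch), 4.2, tolerance = 1e-12)

  inflow <- default_inflow()
  sch20 <- discretize_to_steps(inflow, 20)
  expect_equal(
    time_weighted_average(sch20),
    time_weighted_average(inflow),
    tolerance = 1e-12
  )
  # aligned grid: n_steps = sample count
  set.seed(9)
  w <- random_waveform(32, lo = 0.5, hi = 4)
  sch <- discretize_to_steps(w, 32)
  expect_equal(time_weighted_average(sch), time_weighted_average(w), tolerance = 1e-12)
  expect_error(discretize_to_steps(w, 1), class = "venaloop_config_error")
})

test_that("negative lobes are clipped only at the schedule stage", {
  n <- 32
  t <- (0:(n - 1)) / n
  w <- flow_waveform(t, 2 * sin(2 * pi * t), 1) # negative half-cycle
  sch <- discretize_to_steps(w, 16)
  expect_true(all(sch$flow_lpm >= 0))
  expect_true(any(w$flow_lpm < 0))
  # clipping biases the schedule TWA upward relative to the waveform
  expect_gte(time_weighted_average(sch), time_weighted_average(w))
})

test_that("constant_waveform rejects negative flow", {
  expect_error(constant_waveform(-1), class = "venaloop_domain_error")
})

test_that("waveform CSV round-trips with TWA preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  inflow <- default_inflow(64)
  write_waveform_csv(inflow, path)
  back <- read_waveform_csv(path)
  expect_equal(back$flow_lpm, inflow$flow_lpm, tolerance = 1e-9)
  expect_equal(wave_period(back), wave_period(inflow), tolerance = 1e-9)
  expect_equal(
    time_weighted_average(back),
    time_weighted_average(inflow),
    tolerance = 1e-9
  )
  first_line <- readLines(path, n = 1)
  expect_identical(first_line, "time_s,flow_lpm")
})

test_that("unit round trip L/min -> cm^3/s -> L/min is the identity", {
  x <- c(0, 0.1, 3.1, 6, 123.45)
  expect_equal(venaloop:::cm3s_to_lpm(venaloop:::lpm_to_cm3s(x)), x, tolerance = 1e-12)
  expect_equal(venaloop:::lpm_to_cm3s(3), 50)
})
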