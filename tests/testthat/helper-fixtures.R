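# Shared fixtures built in code.

default_inflow <- function(n_samples = 256L) {
  p <- venous_waveform_params()
  pump_inflow_profile(
    venous_waveform(p, "svc", n_samples),
    venous_waveform(p, "ivc", n_samples)
  )
}

# random waveform on a shared grid; sign-free flows for analytic checks
random_waveform <- function(n = 32L, period = 1, lo = -1, hi = 5) {
  times <- (seq_len(n) - 1L) * period / n
  flow_waveform(times, stats::runif(n, lo, hi), period)
}

noiseless_sensor <- function(ppl = 396) {
  turbine_sensor(pulses_per_liter = ppl, window_s = 10, count_jitter_sd = 0)
}
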