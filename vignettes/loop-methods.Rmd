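---
title: "Models and methods behind venaloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind venaloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venaloop)
```

venaloop simulates a venous mock circulatory loop end to end: waveform
synthesis, split-tube hydraulics, pump control and calibration, turbine
flow sensing, reservoir heating, and the anatomical verification rules
applied to the as-built hardware. This vignette explains each model, its
assumptions, the parameters that matter, and the numerical choices, so
that a reader can judge what a passing test suite does — and does not —
say about a physical loop.

## The venous waveform family

Physiological vena-cava flow is biphasic: a systolic peak (S wave), a
diastolic peak (D wave), and a brief flow reduction or reversal around
atrial contraction. Published patient waveforms are not available here in
tabulated form, so the package defines a parametric family that reproduces
this qualitative morphology while keeping every derived quantity analytic:

$$F(t) = m_b\left[1 + \alpha_S\,c(t;t_S,w_S) + \alpha_D\,c(t;t_D,w_D)
  - \alpha_A\,c(t;t_A,w_A)\right]$$

where $c(t;t_0,w) = \tfrac12\bigl(1+\cos(2\pi (t-t_0)/w)\bigr)$ on
$|t-t_0|\le w/2$ (periodically wrapped) and 0 elsewhere. Centers and
widths are fractions of the period, so changing the heart rate rescales
the waveform in time without changing its cycle mean. After shaping, the
baseline $m_b$ is set multiplicatively so the cycle mean equals the branch
target exactly; this makes the downstream time-weighted averages exact by
construction rather than approximately tuned.

Defaults: heart rate 60 bpm (resting; period 1 s); total venous return
3.10 L/min, the loop's pulsatile operating point; SVC fraction 1/3 (the
physiological SVC:IVC ≈ 1:2 split of venous return); systolic lobe
$\alpha_S=0.8$ at $0.25T$ (width $0.25T$), diastolic lobe $\alpha_D=0.5$
at $0.65T$ (width $0.25T$), atrial dip $\alpha_A=0.3$ at $0.95T$ (width
$0.15T$). With these amplitudes the waveform never goes negative
($1-\alpha_A > 0$); negative flows in other configurations are permitted
in the analytic waveform and clipped only when discretizing to the pump
schedule, because the impeller pump is unidirectional.

What this emulates — and does not. The family captures the biphasic S/D
morphology, branch mean split, and heart-rate scaling. It does not capture
respiratory modulation, beat-to-beat variability, reflected pressure
waves, or vessel compliance (there are no Windkessel elements); passing
tests therefore validate the software chain at physiologically shaped
inputs, not hemodynamic realism of any particular patient.

## Split-tube continuity and wall shear

Internally all hydraulics are cgs (cm, g, s; flow in cm³/s), with L/min
at user-facing boundaries (1 L/min = 1000/60 cm³/s). The chain is
$A = \pi d^2/4$, $v = F/A$,

$$v_{IN} = \frac{v_{SVC} d_{SVC}^2 + v_{IVC} d_{IVC}^2}{d_{IN}^2},
\qquad F_{IN} = v_{IN} A_{IN},$$

applied sample-wise to the two branch waveforms. Algebraically
$F_{IN} = F_{SVC} + F_{IVC}$ — the $d_{IN}^2$ cancels — which the tests
assert to $10^{-12}$ relative tolerance for randomized inputs. The
pump-side inlet diameter is therefore inconsequential for flows; it
defaults to 2.0 cm, the largest loop tubing size, and is configurable.
As-built branch diameters default to the loop's tubing: SVC 1.27 cm
(½ in), IVC 2.0 cm (¾ in).

Wall shear uses the Poiseuille wall formulas $\tau_w = 4\mu F/(\pi r^3)$
(dyn/cm², also reported in Pa) and $\gamma_w = 4F/(\pi r^3)$ (s⁻¹), with
viscosity in cP converted to poise. These assume fully developed laminar
Newtonian flow in straight rigid tubes — adequate for a water-filled
bench loop, not for blood's shear-thinning (Casson) behaviour, which is
out of scope; the working fluid is a configurable Newtonian viscosity
(water, 1.0 cP, by default).

## Time-weighted averages and the step schedule

The pulsatile validation statistic is the time-weighted average (TWA):
the flow integral over one cycle divided by the period. For sampled
waveforms the package integrates the piecewise-linear periodic
interpolant (trapezoid with periodic closure), which on a uniform grid
reduces to the mean of the samples. Waveforms require at least 8 samples
on a uniform grid (spacing tolerance $10^{-9}$ s); the shipped default is
256 samples per cycle.

The pump runs a timed stepping function, represented as a step schedule:
`n_steps` equal sub-intervals per cycle (default 20 — the controller runs
a coarse stepped approximation of the profile; the exact hardware count
is not critical and is configurable), each carrying the exact mean of the
piecewise-linear waveform over its sub-interval, clipped at zero. Because
step means are computed by exact trapezoidal integration on the union of
sample and step breakpoints, the schedule's TWA equals the waveform's
exactly whenever no clipping occurs; tests assert this to $10^{-12}$
relative.

## Pump model and calibration

No pump curve is published for the loop's impeller pump, so the model is
the simplest one consistent with PWM drive: affine above a deadband,
`raw = gain·(duty − deadband)` for duty above the deadband (defaults:
deadband 55 counts, gain 0.03 L/min per count, spanning 0–6 L/min on an
8-bit duty), with the pump's physical deviation from the command expressed
as an affine correction `actual = a·raw + b`, floored at zero. A pure
multiplicative correction factor is the special case `b = 0`.

The bucket test emulates the stopwatch procedure: fill time
`t = 60·V/F + ε` seconds with `ε ~ N(0, timing_sd)` (default 0.1 s, a
realistic manual stopwatch jitter), truncated positive by redrawing;
measured flow is `60·V/t`. Noise lives on the *time*, not the flow,
because that is what the procedure actually measures.

Constant-flow verification commands each setpoint as a continuous
(unquantized) duty and regresses measured on set flow by ordinary least
squares (`stats::lm`), with `r² = 1 − SS_res/SS_tot`. Driving the
calibration with continuous duty is a deliberate design choice: it makes
the procedure an unbiased estimator of the pump's `(a, b)` — noiseless
trials recover them to $10^{-9}$ — whereas integer-PWM quantization would
alias a deterministic rounding error into the fit. The integer path
(`duty_for_flow`, `schedule_duties`) is used where the hardware is being
mimicked, with the documented half-gain-step rounding bound. Degenerate
designs (fewer than two distinct setpoints) are errors, and two-point
designs trivially give `r² = 1`.

The bench-reported regression (slope 1.012, intercept −0.0423,
r² = 0.9988) derives from unpublished hardware data; the package treats
it as an emulation target, not a reproduction: a pump configured with
that `(a, b)` generates trials whose fit recovers the coefficients, and
the noisy-slope band [0.95, 1.05] at 3 trials per point is verified over
100 seeds.

## Turbine sensors and multi-cycle averaging

The Hall-effect turbine sensor emits pulses proportional to throughput
volume. Counting over a window integrates the (periodically extended)
flow signal, multiplies by pulses-per-liter, adds Gaussian count jitter
(default SD 2 pulses per window — the simplest noise model consistent
with repeated readings showing spread), rounds, and floors at zero.
Conversion back is `60·(count/window)/pulses_per_liter`, so a noiseless
round trip is exact up to one pulse quantum (`60/(ppl·window)` L/min —
about 0.015 L/min for the default 396 pulses/L over 10 s).

The default 396 pulses/L is the YF-B2's nominal ≈6.6 Hz per L/min
(6.6·60 pulses per liter); in practice the factor comes from
`calibrate_correction_factor()`, which averages the implied factor over
recordings with known flow. The pulsatile measurement repeats a
10-cycle-window reading three times (trial *i* seeded `seed + i − 1`) and
reports mean and sample SD; a single trial reports SD 0 with an explicit
degenerate flag rather than erroring, so report generation never aborts.

## Reservoir heating and the thermostat

The reservoir is a single well-mixed volume:
$mc\,\dot T = P u - k (T - T_{amb})$, with bang-bang hysteresis control
(`u` on below setpoint − deadband/2, off above setpoint + deadband/2,
held inside the band). Defaults: 3 L test volume, 1 kW sous-vide-class
heater, loss coefficient 5 W/°C, ambient 20 °C, c = 4186 J/(kg·°C),
setpoint 37 °C with a 1 °C band matching the loop's 37 ± 1 °C operating
criterion. The heater wattage and loss coefficient are plausible
engineering values (they are not published for the physical loop), so the
simulated steady temperature is a model property checked against the
operating band, not a reproduction of any single bench reading.

Integration is explicit Euler, the natural scheme for a switched linear
system; `dt` must be below a tenth of the thermal time constant
$mc/k$ (≈2512 s at defaults; default `dt` = 1 s) or a stability error is
raised. Left-endpoint Euler makes the discrete energy balance exact —
heater energy minus losses equals $mc\,\Delta T$ — which the tests assert
to rounding error, and the first crossing of the switch-on threshold
matches the closed-form solution of the linear ODE
($t = (mc/k)\ln\frac{P/k - \Delta T_0}{P/k - \Delta T}$ ≈ 216 s from
20 °C) within the step size.

Steady state is the time-average of the trace tail (default: final half).
Convergence requires at least two thermostat switch events in the tail;
as a deliberate extension, a tail that is already steady (range ≤
0.01 °C — e.g. a heater-off relaxation that has reached ambient) counts
as converged, since demanding switch events there would reject a
perfectly settled trace. At the defaults the limit cycle is a slightly
asymmetric sawtooth (fast ≈14 s heat-up, slow ≈150 s cool-down across the
1 °C band) whose time-average sits at 37.0 °C.

## Anatomical verification rules

Heart axes are checked against the *average-heart* literature mean ± 1 SD,
bounds inclusive — the only rule consistent with all five published range
pairs (4.04–4.98, 4.32–5.26, 7.10–8.98, 4.18–5.06, 3.28–4.16 cm). The
shipped as-built values (4.45, 5.08, 7.62, 5.00, 3.81 cm) all pass. For
the midway right-ventricular short axis the tabulated source value
(3.81 cm) and its narrative (4.81 cm) disagree; the package defaults to
3.81 cm — the only value consistent with the claim that all axes fell
within range — and `run_report()` flags the discrepancy in its notes
rather than resolving it silently.

Vessel tubing passes within `k_sd` (default 1) literature SDs of the
anatomical mean, inclusive — the IVC sits exactly on the boundary
(|2.00 − 1.75| = 0.25) and passes. The femoral port is on a structural
exclusion list (reported `excluded`, never failed): it is a short
Tuohy-Borst insertion port whose diameter does not affect the flow path.
Chamber areas are stored for reference only; the physical model's areas
were never measured, so no rule applies.

Access paths: only the 80 cm totals are fixed by the hardware; the
segment split (radial: axillary 30 + subclavian 25 + SVC 25 cm; femoral:
port 5 + IVC line 75 cm) is a package default chosen to be anatomically
ordered and summing to the as-built totals.

Friction: μ = F/N per measurement, mean and sample SD, checked against
the physiological band 0.015 ≤ μ ≤ 0.13 (inclusive) and the design band
0 < μ < 0.5 (strict). The default measurement set is synthetic (bench
force data are unpublished): five pucks at 10 N normal force with
friction forces 1.2, 0.6, 1.8, 1.55, 0.85 N, giving mean 0.12 and
SD ≈ 0.05, matching the reported material characterization.

## Randomness and reproducibility

Every stochastic operation takes an explicit integer seed and scopes its
generator with `withr::with_seed` — no hidden global RNG state. Multi-trial
operations derive trial seeds as `seed + i − 1`, so a three-trial run at
seed 1 uses seeds 1, 2, 3. Tests assert both reproducibility under a
fixed seed and sensitivity to well-separated seeds (adjacent Mersenne
seeds can yield first draws that round to the same pulse count, which is
expected behaviour, not a bug).

## Problem sizes and report conventions

The shipped defaults are sized for interactive use: 256 samples per
waveform cycle, 20 steps per schedule, 12 calibration trials
(4 setpoints × 3), 3 sensor trials over 10 cycles each, and a 3600 s
thermal simulation at 1 s steps; the full test suite runs in a few
seconds. `run_report()` prints numbers at 2 decimal places (L/min, cm)
while all comparisons use full precision; its section pass rules are
package conventions: constant flow passes at slope within 5% of unity
with r² ≥ 0.99, pulsatile flow within 0.13 L/min of the theoretical
average (the loop's observed trial spread), temperature within
setpoint ± deadband, and path lengths equal to the design target. The
report's JSON structure is described by
`inst/schema/loop-report.schema.json`.

## Known limitations

No pressure waveforms or compliance, no CFD (flows are cross-section
averages), no valve or diseased-anatomy flow patterns, no non-Newtonian
rheology, no catheter–wall mechanics, and no real microcontroller timing
(the physical loop's sampling-rate limits are out of scope). The
simulator validates the *verification logic and software chain* of a
loop; agreement here is necessary, not sufficient, for a physical build
to pass its bench tests.
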