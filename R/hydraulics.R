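# Split-tube continuity and Poiseuille wall shear.
#
# Internal units are cgs (flow cm^3/s, length cm, stress dyn/cm^2);
# user-facing flows are L/min and converted at the boundary.

#' Fluid properties of the working fluid
#'
#' @param dynamic_viscosity_cp Dynamic viscosity in centipoise (> 0). Water,
#'   the loop's working fluid, is 1.0 cP.
#' @param density_g_cm3 Mass density in g/cm^3 (> 0).
#'
#' @return A list of class `fluid_properties`.
#' @export
fluid_properties <- function(dynamic_viscosity_cp = 1.0, density_g_cm3 = 1.0) {
  check_scalar_number(dynamic_viscosity_cp, "dynamic_viscosity_cp", positive = TRUE)
  check_scalar_number(density_g_cm3, "density_g_cm3", positive = TRUE)
  structure(
    list(
      dynamic_viscosity_cp = dynamic_viscosity_cp,
      density_g_cm3 = density_g_cm3
    ),
    class = "fluid_properties"
  )
}

#' Cross-sectional area of a circular vessel
#'
#' `A = pi d^2 / 4`.
#'
#' @param diameter Internal diameter in cm (> 0). Vectorized.
#' @return Area in cm^2.
#' @export
#' @examples
#' cross_section_area(2.0) # pi
cross_section_area <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    bad <- diameter[!is.finite(diameter) | diameter <= 0][1]
    stop_domain(sprintf("vessel diameter must be > 0 (got %g cm)", bad))
  }
  pi * (diameter / 2)^2
}

#' Mean velocity from volumetric flow
#'
#' `v = F / A`.
#'
#' @param flow Flow in cm^3/s (sign preserved). Vectorized.
#' @param area Cross-sectional area in cm^2 (> 0).
#' @return Velocity in cm/s.
#' @export
velocity_from_flow <- function(flow, area) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop_domain("cross-sectional area must be > 0")
  }
  flow / area
}

#' Volumetric flow from mean velocity
#'
#' `F = v A`.
#'
#' @param velocity Velocity in cm/s. Vectorized.
#' @param area Cross-sectional area in cm^2 (> 0).
#' @return Flow in cm^3/s.
#' @export
flow_from_velocity <- function(velocity, area) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop_domain("cross-sectional area must be > 0")
  }
  velocity * area
}

#' Combine SVC and IVC branch velocities into the inlet velocity
#'
#' Continuity for a split tube: the inlet (pump-side) velocity needed to
#' supply both vena-cava branches is
#' `v_in = (v_svc d_svc^2 + v_ivc d_ivc^2) / d_in^2`.
#' The `d_in^2` cancels when converting back to flow, so downstream flows do
#' not depend on the inlet diameter.
#'
#' @param v_svc,v_ivc Branch velocities in cm/s. Vectorized.
#' @param d_svc,d_ivc,d_in Branch and inlet internal diameters in cm (> 0).
#' @return Inlet velocity in cm/s.
#' @export
combine_branch_velocities <- function(v_svc, d_svc, v_ivc, d_ivc, d_in) {
  for (d in list(d_svc, d_ivc, d_in)) {
    if (any(!is.finite(d)) || any(d <= 0)) {
      bad <- d[!is.finite(d) | d <= 0][1]
      stop_domain(sprintf("vessel diameter must be > 0 (got %g cm)", bad))
    }
  }
  (v_svc * d_svc^2 + v_ivc * d_ivc^2) / d_in^2
}

#' Pump inflow profile from the two vena-cava waveforms
#'
#' Applies the continuity chain sample-wise: branch flows to velocities, the
#' split-tube combination, then back to flow at the inlet. Mass conservation
#' makes the output flow equal the sum of the branch flows at every sample,
#' independent of `d_in`.
#'
#' @param svc_wave,ivc_wave [flow_waveform()]s on the same period and grid.
#' @param d_svc,d_ivc,d_in Internal diameters in cm; defaults are the loop's
#'   as-built tubing (SVC 1.27 cm, IVC 2.0 cm, inlet 2.0 cm).
#'
#' @return A [flow_waveform()] on the shared grid.
#' @export
#' @examples
#' p <- venous_waveform_params()
#' inflow <- pump_inflow_profile(venous_waveform(p, "svc"), venous_waveform(p, "ivc"))
#' time_weighted_average(inflow) # 3.10 L/min
pump_inflow_profile <- function(svc_wave, ivc_wave,
                                d_svc = 1.27, d_ivc = 2.0, d_in = 2.0) {
  stopifnot(inherits(svc_wave, "flow_waveform"), inherits(ivc_wave, "flow_waveform"))
  if (abs(wave_period(svc_wave) - wave_period(ivc_wave)) > 1e-9 ||
    nrow(svc_wave) != nrow(ivc_wave) ||
    max(abs(svc_wave$time_s - ivc_wave$time_s)) > 1e-9) {
    stop_shape("SVC and IVC waveforms must share the same period and sample grid")
  }
  a_svc <- cross_section_area(d_svc)
  a_ivc <- cross_section_area(d_ivc)
  a_in <- cross_section_area(d_in)
  v_svc <- velocity_from_flow(lpm_to_cm3s(svc_wave$flow_lpm), a_svc)
  v_ivc <- velocity_from_flow(lpm_to_cm3s(ivc_wave$flow_lpm), a_ivc)
  v_in <- combine_branch_velocities(v_svc, d_svc, v_ivc, d_ivc, d_in)
  f_in <- flow_from_velocity(v_in, a_in)
  flow_waveform(svc_wave$time_s, cm3s_to_lpm(f_in), wave_period(svc_wave))
}

#' Poiseuille wall shear stress
#'
#' `tau_w = 4 mu F / (pi r^3)` for fully developed laminar flow of a
#' Newtonian fluid in a straight tube. Viscosity is given in cP and
#' converted to poise internally; the result is dyn/cm^2 (divide by 10
#' for Pa).
#'
#' @param flow Flow in cm^3/s. Vectorized.
#' @param radius Tube internal radius in cm (> 0).
#' @param fluid A [fluid_properties()].
#' @return Wall shear stress in dyn/cm^2.
#' @export
wall_shear_stress <- function(flow, radius, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop_domain("tube radius must be > 0")
  }
  mu_poise <- fluid$dynamic_viscosity_cp * 0.01
  4 * mu_poise * flow / (pi * radius^3)
}

#' Poiseuille wall shear rate
#'
#' `gamma_w = 4 F / (pi r^3)`; equals [wall_shear_stress()] divided by the
#' viscosity in poise.
#'
#' @inheritParams wall_shear_stress
#' @return Wall shear rate in 1/s.
#' @export
wall_shear_rate <- function(flow, radius) {
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop_domain("tube radius must be > 0")
  }
  4 * flow / (pi * radius^3)
}

#' Wall-shear table for a set of vessels at a common flow
#'
#' Evaluates wall shear stress (dyn/cm^2 and Pa) and shear rate for each
#' vessel's as-built diameter at the given flow.
#'
#' @param vessels A vessel table as from [vessel_table()] (needs columns
#'   `vessel` and `system_diameter_cm`).
#' @param flow_lpm Flow in L/min applied to every vessel.
#' @param fluid A [fluid_properties()].
#' @return A tibble with one row per vessel: `vessel`, `diameter_cm`,
#'   `flow_lpm`, `shear_stress_dyn_cm2`, `shear_stress_pa`,
#'   `shear_rate_per_s`.
#' @export
shear_table <- function(vessels, flow_lpm, fluid = fluid_properties()) {
  if (!all(c("vessel", "system_diameter_cm") %in% names(vessels))) {
    stop_shape("`vessels` must have columns `vessel` and `system_diameter_cm`")
  }
  check_scalar_number(flow_lpm, "flow_lpm", non_negative = TRUE)
  f_cgs <- lpm_to_cm3s(flow_lpm)
  r <- vessels$system_diameter_cm / 2
  tau <- wall_shear_stress(f_cgs, r, fluid)
  tibble::tibble(
    vessel = vessels$vessel,
    diameter_cm = vessels$system_diameter_cm,
    flow_lpm = flow_lpm,
    shear_stress_dyn_cm2 = tau,
    shear_stress_pa = dyn_cm2_to_pa(tau),
    shear_rate_per_s = wall_shear_rate(f_cgs, r)
  )
}
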