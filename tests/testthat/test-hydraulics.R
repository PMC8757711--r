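# Split-tube continuity chain and Poiseuille wall shear.

test_that("cross-sectional area follows pi d^2/4 and rejects degenerate diameters", {
  expect_equal(cross_section_area(2.0), pi)
  expect_equal(cross_section_area(1.27), pi * 1.27^2 / 4, tolerance = 1e-12)
  expect_equal(round(cross_section_area(1.27), 5), 1.26677)
  expect_error(cross_section_area(0), class = "venaloop_domain_error")
  expect_error(cross_section_area(-1), "-1")
})

test_that("velocity and flow conversions are exact inverses and preserve sign", {
  expect_equal(velocity_from_flow(pi, pi), 1.0)
  expect_equal(velocity_from_flow(50, pi), 50 / pi, tolerance = 1e-12)
  expect_equal(velocity_from_flow(0, 3.7), 0)
  expect_equal(flow_from_velocity(1.0, pi), pi)
  expect_equal(flow_from_velocity(-1.0, 2.0), -2.0)
  expect_error(velocity_from_flow(1, 0), class = "venaloop_domain_error")
  expect_error(flow_from_velocity(1, -2), class = "venaloop_domain_error")
  # round trip at random areas
  set.seed(11)
  f <- runif(20, -10, 10)
  a <- runif(20, 0.1, 10)
  expect_equal(flow_from_velocity(velocity_from_flow(f, a), a), f, tolerance = 1e-12)
})

test_that("branch-velocity combination matches the continuity formula", {
  expect_equal(
    combine_branch_velocities(10, 1.27, 10, 2.0, 2.0),
    (10 * 1.27^2 + 10 * 4) / 4,
    tolerance = 1e-12
  )
  expect_equal(round(combine_branch_velocities(10, 1.27, 10, 2.0, 2.0), 3), 14.032)
  # symmetric case: equal velocities with d_in^2 = d_svc^2 + d_ivc^2 return v
  expect_equal(
    combine_branch_velocities(3, 1.5, 3, 2.0, sqrt(1.5^2 + 2^2)),
    3,
    tolerance = 1e-12
  )
  expect_equal(combine_branch_velocities(0, 1, 0, 2, 3), 0)
  expect_error(combine_branch_velocities(1, 0, 1, 2, 2), class = "venaloop_domain_error")
})

test_that("the continuity chain continues consistently to inlet flow", {
  v_in <- combine_branch_velocities(10, 1.27, 10, 2.0, 2.0)
  f_in <- flow_from_velocity(v_in, cross_section_area(2.0))
  expect_equal(f_in, 44.0836, tolerance = 1e-5)
  # equals the branch flow sum
  expect_equal(
    f_in,
    flow_from_velocity(10, cross_section_area(1.27)) + flow_from_velocity(10, cross_section_area(2.0)),
    tolerance = 1e-12
  )
})

test_that("pump inflow conserves mass sample-wise regardless of inlet diameter", {
  w1 <- constant_waveform(1, 1, 16)
  w2 <- constant_waveform(2, 1, 16)
  out <- pump_inflow_profile(w1, w2, d_svc = 1.27, d_ivc = 2.0, d_in = 5.0)
  expect_equal(out$flow_lpm, rep(3, 16), tolerance = 1e-12)
  # svc zero: output equals ivc wave sample-wise
  set.seed(7)
  ivc <- random_waveform(32, lo = 0, hi = 4)
  zero <- flow_waveform(ivc$time_s, rep(0, 32), 1)
  expect_equal(
    pump_inflow_profile(zero, ivc)$flow_lpm,
    ivc$flow_lpm,
    tolerance = 1e-12
  )
  # randomized conservation property, arbitrary d_in
  for (seed in 1:5) {
    set.seed(seed)
    a <- random_waveform(32)
    b <- random_waveform(32)
    d_in <- runif(1, 0.5, 6)
    out <- pump_inflow_profile(a, b, d_svc = 1.1, d_ivc = 2.3, d_in = d_in)
    expect_equal(out$flow_lpm, a$flow_lpm + b$flow_lpm, tolerance = 1e-12)
  }
})

test_that("mismatched waveform grids are rejected", {
  a <- constant_waveform(1, 1, 16)
  b <- constant_waveform(1, 2, 16)
  expect_error(pump_inflow_profile(a, b), class = "venaloop_shape_error")
  c <- constant_waveform(1, 1, 32)
  expect_error(pump_inflow_profile(a, c), class = "venaloop_shape_error")
})

test_that("wall shear stress and rate follow the Poiseuille formulas", {
  water <- fluid_properties(1.0)
  expect_equal(
    wall_shear_stress(50, 0.635, water),
    4 * 0.01 * 50 / (pi * 0.635^3),
    tolerance = 1e-12
  )
  expect_equal(round(wall_shear_stress(50, 0.635, water), 3), 2.486)
  expect_equal(round(wall_shear_rate(50, 0.635), 1), 248.6)
  expect_equal(wall_shear_stress(0, 1, water), 0)
  expect_equal(wall_shear_rate(0, 1), 0)
  # doubling viscosity doubles stress
  expect_equal(
    wall_shear_stress(50, 0.635, fluid_properties(2.0)),
    2 * wall_shear_stress(50, 0.635, water),
    tolerance = 1e-12
  )
  expect_error(wall_shear_stress(1, 0, water), class = "venaloop_domain_error")
  expect_error(wall_shear_rate(1, -1), class = "venaloop_domain_error")
})

test_that("tau_w = mu * gamma_w for randomized inputs", {
  set.seed(42)
  for (i in 1:20) {
    f <- runif(1, 0, 200)
    r <- runif(1, 0.1, 2)
    mu_cp <- runif(1, 0.5, 5)
    fl <- fluid_properties(mu_cp)
    expect_equal(
      wall_shear_stress(f, r, fl),
      mu_cp * 0.01 * wall_shear_rate(f, r),
      tolerance = 1e-12
    )
  }
})

test_that("shear table reports both dyn/cm^2 and Pa for every vessel", {
  tab <- shear_table(vessel_table(), 3.10)
  expect_equal(nrow(tab), nrow(vessel_table()))
  expect_equal(tab$shear_stress_pa, tab$shear_stress_dyn_cm2 / 10, tolerance = 1e-12)
  svc <- tab[tab$vessel == "superior_vena_cava", ]
  expect_equal(
    svc$shear_stress_dyn_cm2,
    4 * 0.01 * (3.10 * 1000 / 60) / (pi * (1.27 / 2)^3),
    tolerance = 1e-12
  )
})
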