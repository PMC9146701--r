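test_that("SG derivative equals the brute-force local polyfit oracle", {
  withr::with_seed(11, {
    x <- seq(0, 1, length.out = 25)
    for (p in c(1L, 2L)) for (w in c(7L, 9L)) {
      y <- sin(6 * x) + 0.05 * rnorm(25)
      expect_lt(max(abs(sg_derivative(y, x, w, p) -
                          polyfit_derivative(y, x, w, p))), 1e-10)
    }
  })
})

test_that("SG derivative reproduces polynomials and flags bad input", {
  x <- seq(0, 2, length.out = 15)
  expect_equal(sg_derivative(3 * x + 2, x), rep(3, 15), tolerance = 1e-10)
  expect_equal(sg_derivative(rep(5, 15), x), rep(0, 15), tolerance = 1e-12)
  expect_error(sg_derivative(x, x, window = 6), "odd")
  expect_error(sg_derivative(x, x, window = 17), "exceeds")
  expect_error(sg_derivative(x, x, poly_order = 7), "smaller than window")
  expect_error(sg_derivative(x, x^2), "resample")
})

test_that("rigid-body rotation gives zero shear rate", {
  r <- seq(10e-3, 11e-3, length.out = 21)
  prof <- velocity_profile(r, 0.7 * r)
  expect_lt(max(shear_rate_profile(prof)), 1e-10)
})

test_that("Newtonian profile reproduces the analytic shear rate", {
  geom <- default_geom
  om <- rotor_rate_from_applied(5, geom)
  sol <- couette_forward_solve(geom, hb_params(0, 1, 1), om)
  gdot <- shear_rate_profile(sol$profile)
  r <- sol$profile$r
  exact <- 2 * om * geom$inner_radius^2 * geom$outer_radius^2 /
    (r^2 * (geom$outer_radius^2 - geom$inner_radius^2))
  interior <- 4:(length(r) - 3)
  expect_equal(gdot[interior], exact[interior], tolerance = 1e-3)
})

test_that("beyond the yield radius the reconstructed shear rate vanishes", {
  geom <- default_geom
  sol <- couette_forward_solve(geom, hb_params(500, 30, 0.47),
                               rotor_rate_from_applied(0.5, geom))
  gdot <- shear_rate_profile(sol$profile)
  frozen <- sol$profile$r > sol$yield_radius + 4 * 48.8e-6
  expect_true(any(frozen))
  expect_lt(max(gdot[frozen]), 0.05)
})

test_that("noiseless LFCs round-trip the generating HB law within 1%", {
  geom <- default_geom
  om <- rotor_rate_from_applied(5, geom)
  for (tau0 in c(0, 50, 100, 300)) for (n in c(0.3, 0.47, 1.0)) {
    hb <- hb_params(tau0, 30, n)
    sol <- couette_forward_solve(geom, hb, om)
    lfc <- assemble_lfc(sol$profile, sol$torque, geom)
    expect_gte(length(lfc$gamma_dot), 10)
    rel <- abs(lfc$sigma - hb_stress(hb, lfc$gamma_dot)) / lfc$sigma
    expect_lt(max(rel), 0.01)
    # monotone: stress decreasing, shear rate non-increasing with radius
    ord <- order(lfc$r)
    expect_true(all(diff(lfc$sigma[ord]) < 0))
    expect_true(all(diff(lfc$gamma_dot[ord]) < 1e-10))
  }
})

test_that("masking removes unresolvable and wall-adjacent points", {
  geom <- default_geom
  sol <- couette_forward_solve(geom, hb_params(80, 30, 0.47),
                               rotor_rate_from_applied(5, geom))
  full <- assemble_lfc(sol$profile, sol$torque, geom, mask_threshold = 0,
                       mask_edges = FALSE)
  masked <- assemble_lfc(sol$profile, sol$torque, geom)
  expect_equal(length(full$gamma_dot), length(sol$profile$r))
  expect_equal(length(masked$gamma_dot), length(sol$profile$r) - 6)
  # zero torque with zero velocity: everything masked
  r <- seq(10e-3, 11e-3, length.out = 21)
  silent <- velocity_profile(r, rep(0, 21))
  empty <- assemble_lfc(silent, 0, geom)
  expect_length(empty$gamma_dot, 0)
})

test_that("time-stamp pairing is enforced", {
  geom <- default_geom
  sol <- couette_forward_solve(geom, hb_params(80, 30, 0.47), 0.5)
  prof <- sol$profile
  prof$time_stamp <- 30
  expect_error(assemble_lfc(prof, sol$torque, geom, torque_time = 90),
               "does not match")
  expect_s3_class(assemble_lfc(prof, sol$torque, geom, torque_time = 30),
                  "local_flow_curve")
})

test_that("partially yielded profiles give narrower flow curves", {
  geom <- default_geom
  om <- rotor_rate_from_applied(0.5, geom)
  loc <- couette_forward_solve(geom, hb_params(500, 30, 0.47), om)
  ful <- couette_forward_solve(geom, hb_params(50, 30, 0.47), om)
  lfc_loc <- assemble_lfc(loc$profile, loc$torque, geom)
  lfc_ful <- assemble_lfc(ful$profile, ful$torque, geom)
  # localization freezes part of the gap: fewer usable points there
  expect_lt(length(lfc_loc$gamma_dot), length(lfc_ful$gamma_dot))
})

test_that("profile constructor validates its invariants", {
  r <- seq(10e-3, 11e-3, length.out = 21)
  expect_error(velocity_profile(r[1:6], rep(0, 6)), "at least 7")
  expect_error(velocity_profile(rev(r), rep(0, 21)), "ascending")
  expect_error(velocity_profile(r, rep(0, 20)), "same length")
  expect_error(local_flow_curve(c(-1, 1, 2), c(3, 2, 1)), "non-negative")
  expect_error(local_flow_curve(1:3, c(1, 2, 3), r = r[1:3]),
               "strictly decreasing")
})
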