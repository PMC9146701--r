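test_that("sphere eigenvalue roots satisfy the boundary condition", {
  x <- sphere_bessel_roots(10)
  expect_equal(x[1], 2.0815759778, tolerance = 1e-8)
  bc <- (x^2 - 2) * sin(x) + 2 * x * cos(x)
  expect_lt(max(abs(bc)), 1e-8)
  expect_true(all(diff(x) > 2.9 & diff(x) < 4))
  expect_equal(diff(x)[9], pi, tolerance = 0.01)  # asymptotic spacing
})

test_that("no gradient means no attenuation", {
  p <- pgse_params(c(0, 0.5, 1), delta = 2e-3, Delta = 211e-3)
  E <- murday_cotts_attenuation(1.7e-6, 4e-12, p)
  expect_identical(E[1], 1)
  expect_true(all(E > 0 & E <= 1))
  expect_true(all(diff(E) < 0))
})

test_that("large spheres approach free (Stejskal-Tanner) diffusion", {
  p <- pgse_params(c(0.2, 0.5), delta = 1e-3, Delta = 211e-3)
  for (D in c(4e-12, 1e-11)) {
    free <- exp(-stejskal_tanner_b(p) * D)
    dev <- vapply(c(50, 100, 200), function(mult) {
      E <- murday_cotts_attenuation(mult * sqrt(D * p$Delta), D, p,
                                    n_roots = 2000)
      max(abs(E - free) / free)
    }, numeric(1))
    expect_lt(dev[3], 0.01)          # near-free at R = 200 sqrt(D Delta)
    expect_true(all(diff(dev) < 0))  # monotone approach to the limit
  }
})

test_that("tiny spheres show full motional narrowing", {
  p <- pgse_params(c(1, 4), delta = 2e-3, Delta = 211e-3)
  D <- 4e-12
  E <- murday_cotts_attenuation(0.01 * sqrt(D * p$delta), D, p)
  expect_equal(E, c(1, 1), tolerance = 1e-6)
})

test_that("series truncation is checked and reported", {
  p <- pgse_params(c(0.5), delta = 1e-3, Delta = 211e-3)
  D <- 4e-12
  expect_error(
    murday_cotts_attenuation(100 * sqrt(D * p$Delta), D, p, n_roots = 3),
    "n_roots")
})

test_that("lognormal averaging degenerates and converges correctly", {
  p <- minispec_pgse
  mono <- pfg_decay_lognormal(3.39, 0, 4e-12, p)
  single <- murday_cotts_attenuation(3.39e-6 / 2, 4e-12, p)
  expect_equal(mono$attenuation, single, tolerance = 1e-12)

  d64 <- pfg_decay_lognormal(3.39, 0.2, 4e-12, p, quadrature_nodes = 64)
  d128 <- pfg_decay_lognormal(3.39, 0.2, 4e-12, p, quadrature_nodes = 128)
  expect_lt(max(abs(d64$attenuation - d128$attenuation)), 1e-4)
  expect_true(all(diff(d64$attenuation) < 0))

  pz <- pgse_params(c(0, seq(0.5, 3, length.out = 6)), 2e-3, 211e-3)
  expect_identical(pfg_decay_lognormal(3.39, 0.2, 4e-12, pz)$attenuation[1],
                   1)
})
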