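test_that("noiseless decays invert to the generating distribution", {
  dec <- pfg_decay_lognormal(3.39, 0.20, 4e-12, minispec_pgse)
  fit <- fit_droplet_size(dec, minispec_pgse)
  expect_equal(fit$D33, 3.39, tolerance = 0.01)
  expect_equal(fit$alpha, 0.20, tolerance = 0.01)
})

test_that("a monodisperse emulsion fits with near-zero width", {
  dec <- pfg_decay_lognormal(3.39, 0, 4e-12, minispec_pgse)
  fit <- fit_droplet_size(dec, minispec_pgse)
  expect_lt(fit$alpha, 0.02)
  expect_equal(fit$D33, 3.39, tolerance = 0.01)
})

test_that("under-encoded decays are rejected with a clear error", {
  weak <- pgse_params(seq(0.01, 0.3, length.out = 8), 2e-3, 211e-3)
  dec <- pfg_decay_lognormal(3.39, 0.2, 4e-12, weak)
  expect_error(fit_droplet_size(dec, weak), "under-encoded")
  few <- pfg_decay(c(0.5, 1, 2), c(0.9, 0.7, 0.4))
  expect_error(fit_droplet_size(few, minispec_pgse), "at least 6")
})

test_that("D33 is recovered within 3% in the median at 0.5% noise", {
  for (cs in list(c(3.39, 0.20), c(4.30, 0.40))) {
    errs <- vapply(1:25, function(s) {
      dec <- pfg_decay_lognormal(cs[1], cs[2], 4e-12, minispec_pgse,
                                 noise = noise_spec(0.005, s, "additive"))
      abs(fit_droplet_size(dec, minispec_pgse)$D33 - cs[1]) / cs[1]
    }, numeric(1))
    expect_lt(stats::median(errs), 0.03)
  }
})

test_that("the fitted model curve is monotone in gradient strength", {
  dec <- pfg_decay_lognormal(3.39, 0.2, 4e-12, minispec_pgse,
                             noise = noise_spec(0.005, 2, "additive"))
  fit <- fit_droplet_size(dec, minispec_pgse)
  curve <- pfg_decay_lognormal(fit$D33, fit$alpha, fit$D_oil,
                               minispec_pgse)$attenuation
  expect_true(all(diff(curve) < 0))
})

test_that("D_oil misspecification propagates as a bounded, monotone bias", {
  # at micrometre droplet sizes and Delta = 211 ms the decay constrains a
  # combination of droplet size and oil diffusivity, which is exactly why
  # D_oil is fixed to a known value instead of fitted; a +-25% error in
  # that value biases D33 smoothly rather than catastrophically
  dec <- pfg_decay_lognormal(3.39, 0.20, 4e-12, minispec_pgse)
  base <- fit_droplet_size(dec, minispec_pgse, D_oil = 4e-12)$D33
  lo <- fit_droplet_size(dec, minispec_pgse, D_oil = 3e-12)$D33
  hi <- fit_droplet_size(dec, minispec_pgse, D_oil = 5e-12)$D33
  expect_equal(base, 3.39, tolerance = 1e-4)
  expect_lt(abs(lo - base) / base, 0.5)
  expect_lt(abs(hi - base) / base, 0.5)
})

test_that("growth ratios reproduce simple diameter quotients", {
  expect_equal(round(growth_ratio(4.30, 3.39), 2), 1.27)
  expect_equal(round(growth_ratio(4.85, 3.84), 2), 1.26)
  dec <- pfg_decay_lognormal(3.39, 0.2, 4e-12, minispec_pgse)
  fit <- fit_droplet_size(dec, minispec_pgse)
  expect_equal(growth_ratio(fit, fit), 1)
  expect_error(growth_ratio(4.3, 0), "positive")
})
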