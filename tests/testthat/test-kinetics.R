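test_that("the structural-kinetic decay has the right limits and shape", {
  p <- skm_params(80.1, 44, 0.012)
  expect_identical(skm_model(p, 0), 80.1)
  expect_equal(skm_model(p, 1e12), 44, tolerance = 1e-9)
  # half the decay is done when ks * t = 1
  expect_equal(skm_model(p, 1 / 0.012), 62.05, tolerance = 1e-12)
  tt <- seq(0, 500, length.out = 200)
  expect_true(all(diff(skm_model(p, tt)) < 0))
})

test_that("SKM fit recovers noiseless parameters exactly", {
  tt <- seq(0, 500, length.out = 20)
  fit <- fit_skm(tt, skm_model(skm_params(80.1, 44, 0.012), tt),
                 time_unit = "min")
  expect_equal(fit$params$tau00, 80.1, tolerance = 1e-6)
  expect_equal(fit$params$tau0e, 44, tolerance = 1e-6)
  expect_equal(fit$params$ks, 0.012, tolerance = 1e-6)
  expect_equal(fit$breakdown_ratio, 80.1 / 44, tolerance = 1e-6)
  expect_identical(fit$time_unit, "min")
})

test_that("a flat series is flagged and returns ks = 0", {
  expect_warning(fit <- fit_skm(c(0, 10, 20, 30), rep(55, 4)),
                 "unidentifiable")
  expect_identical(fit$params$ks, 0)
  expect_identical(fit$breakdown_ratio, 1)
  expect_identical(fit$flags, "flat")
})

test_that("a series far from equilibrium raises the identifiability flag", {
  p <- skm_params(80, 40, 0.0001)
  tt <- seq(0, 500, length.out = 10)
  expect_warning(fit <- fit_skm(tt, skm_model(p, tt)), "equilibrium")
  expect_true("equilibrium_unreached" %in% fit$flags)
})

test_that("the median recovered ks stays within 10% at 5% noise", {
  tt <- seq(0, 500, length.out = 20)
  truth <- skm_params(80.1, 44, 0.012)
  ks_hat <- vapply(1:50, function(s) {
    y <- apply_noise(skm_model(truth, tt),
                     noise_spec(0.05, s, "multiplicative"))
    fit_skm(tt, y)$params$ks
  }, numeric(1))
  expect_equal(stats::median(ks_hat), 0.012, tolerance = 0.10)
})

test_that("breakdown ratios follow from the fitted parameters", {
  expect_equal(round(breakdown_ratio(skm_params(80.1, 44, 0.012)), 2), 1.82)
  expect_equal(round(breakdown_ratio(skm_params(271, 182, 0.11)), 2), 1.49)
  expect_identical(breakdown_ratio(skm_params(55, 55, 0)), 1)
  expect_error(breakdown_ratio(skm_params(10, 0, 0.1)), "positive")
})

test_that("fit preconditions are enforced", {
  expect_error(fit_skm(c(0, 1, 2), c(3, 2, 1)), "at least 4")
  expect_error(fit_skm(rep(0, 5), rep(1, 5)), "positive")
})
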