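test_that("HB fit recovers noiseless parameters exactly", {
  fit <- fit_hb(law_lfc(100, 30, 0.47))
  expect_equal(fit$params$tau0, 100, tolerance = 1e-6)
  expect_equal(fit$params$K, 30, tolerance = 1e-6)
  expect_equal(fit$params$n, 0.47, tolerance = 1e-6)
  # the zero-shear limit of the fitted law is the yield stress
  expect_equal(hb_stress(fit$params, 0), fit$params$tau0)
})

test_that("Newtonian data recover viscosity with zero yield stress", {
  fit <- fit_hb(law_lfc(0, 2.5, 1))
  expect_equal(fit$params$tau0, 0, tolerance = 1e-6)
  expect_equal(fit$params$K, 2.5, tolerance = 1e-6)
  expect_equal(fit$params$n, 1, tolerance = 1e-5)
})

test_that("fixed-n fits work with three points and degenerate input errors", {
  lfc3 <- local_flow_curve(c(1, 5, 20),
                           hb_stress(hb_params(50, 30, 0.47), c(1, 5, 20)))
  fit <- fit_hb(lfc3, n_fixed = 0.47)
  expect_equal(fit$params$tau0, 50, tolerance = 1e-6)
  expect_true(fit$n_fixed)
  expect_error(fit_hb(lfc3), "at least 4")
  same <- local_flow_curve(rep(2, 5), rep(60, 5))
  expect_error(fit_hb(same, n_fixed = 0.47), "distinct|degenerate")
})

test_that("parameter recovery under 1% noise is accurate in the median", {
  # working points whose viscous stress is not swamped by the yield
  # stress, sampled as a well-resolved 32-step flow sweep
  gd32 <- exp(seq(log(0.5), log(20), length.out = 32))
  cases <- list(c(100, 30, 0.47), c(80, 30, 0.8), c(0, 5, 1))
  for (cs in cases) {
    errs <- vapply(1:100, function(s) {
      lfc <- law_lfc(cs[1], cs[2], cs[3], gamma_dot = gd32,
                     noise = noise_spec(0.01, s, "multiplicative"))
      f <- fit_hb(lfc)
      c(if (cs[1] > 0) abs(f$params$tau0 - cs[1]) / cs[1] else 0,
        abs(f$params$K - cs[2]) / cs[2],
        abs(f$params$n - cs[3]) / cs[3])
    }, numeric(3))
    expect_lt(max(apply(errs, 1, stats::median)), 0.05)
  }
})

test_that("global-n fit shares one flow index and matches fit_hb when single", {
  lfcs <- law_lfc_series()
  gfit <- fit_hb_global_n(lfcs)
  expect_equal(gfit$n, 0.47, tolerance = 0.01)
  tau0s <- skm_model(skm_params(80.1, 44, 0.012),
                     c(0, 30, 90, 180, 330, 500))
  expect_equal(gfit$yield_stress_series$tau0, tau0s, tolerance = 1e-4)
  single <- fit_hb_global_n(lfcs[1])
  expect_s3_class(single, "hb_fit")
  expect_equal(single$params$tau0, fit_hb(lfcs[[1]])$params$tau0)
})

test_that("noisy global-n fits preserve the decaying tau0 sequence", {
  lfcs <- law_lfc_series(sigma_noise = 0.02, seed = 5)
  gfit <- fit_hb_global_n(lfcs)
  tau0_true <- skm_model(skm_params(80.1, 44, 0.012),
                         c(0, 30, 90, 180, 330, 500))
  rel <- abs(gfit$yield_stress_series$tau0 - tau0_true) / tau0_true
  expect_lt(stats::median(rel), 0.1)
  # generated monotone decreasing: recovered sequence respects the trend
  expect_lt(stats::cor(gfit$yield_stress_series$tau0,
                       seq_along(tau0_true), method = "spearman"), 0)
})

test_that("joint fit never loses to per-curve fits clamped at the shared n", {
  lfcs <- law_lfc_series(sigma_noise = 0.02, seed = 9)
  gfit <- fit_hb_global_n(lfcs)
  clamped <- sum(vapply(lfcs, function(l)
    fit_hb(l, n_fixed = gfit$n)$residual_norm^2, 0))
  expect_lte(gfit$residual_norm^2, clamped * (1 + 1e-8))
})

test_that("dimensionless scaling matches direct evaluation", {
  props <- emulsion_properties(0.01, 1e-3, 1.7e-6, 0.82)
  hb <- hb_params(100, 30, 0.47)
  pt <- dimensionless_viscous_stress(hb, props, 5)
  expect_equal(pt$scaled_viscous_stress, 30 * 5^0.47 * 1.7e-6 / 0.01,
               tolerance = 1e-12)
  expect_equal(pt$Ca, 1e-3 * 5 * 1.7e-6 / 0.01, tolerance = 1e-12)
  zero <- dimensionless_viscous_stress(hb, props, 0)
  expect_identical(unlist(zero), c(Ca = 0, scaled_viscous_stress = 0))
  props2 <- emulsion_properties(0.01, 1e-3, 2 * 1.7e-6, 0.82)
  pt2 <- dimensionless_viscous_stress(hb, props2, 5)
  expect_equal(pt2$Ca / pt$Ca, 2)
  expect_equal(pt2$scaled_viscous_stress / pt$scaled_viscous_stress, 2)
})

test_that("curves differing only in yield stress collapse when scaled", {
  props <- emulsion_properties(0.01, 1e-3, 1.7e-6, 0.82)
  gd <- exp(seq(log(0.5), log(20), length.out = 12))
  fits <- lapply(c(40, 80, 120), function(t0) fit_hb(law_lfc(t0, 30, 0.47)))
  scaled <- lapply(fits, dimensionless_viscous_stress, props = props,
                   gamma_dot = gd)
  for (k in 2:3)
    expect_lt(max(abs(scaled[[k]]$scaled_viscous_stress -
                        scaled[[1]]$scaled_viscous_stress)), 1e-6)
})
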