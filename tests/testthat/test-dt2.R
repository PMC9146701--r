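# small, fast instances for the inversion mathematics
small_dataset <- function(components, noise = NULL, n_echo = 32L,
                          g = c(0, seq(0.2, 6.6, length.out = 15))) {
  p <- pgse_params(g, 1e-3, 200e-3)
  dt2_signal(components, p, 2.2e-3 * seq_len(n_echo), noise = noise)
}

test_that("kernel matrices are exponential in both dimensions", {
  ds <- small_dataset(data.frame(amplitude = 1, D = 9e-10, T2 = 0.4))
  ker <- build_kernels(ds, log_grid(1e-13, 1e-8, 16), log_grid(1e-3, 3, 16))
  expect_equal(ker$K1[1, ], rep(1, 16))  # g = 0 encodes nothing
  expect_equal(ker$K2[1, ], exp(-2.2e-3 / log_grid(1e-3, 3, 16)))
  # diffusion weighting by direct evaluation of gamma^2 g^2 delta^2 (Delta - delta/3)
  b_direct <- (2.6752218744e8)^2 * 6.6^2 * (1e-3)^2 * (0.2 - 1e-3 / 3)
  expect_equal(max(ker$b), b_direct, tolerance = 1e-12)
  expect_equal(b_direct, 6.224e11, tolerance = 1e-3)
})

test_that("a single on-grid component is recovered sharply", {
  Dg <- log_grid(1e-13, 1e-8, 32)
  Tg <- log_grid(1e-3, 3, 32)
  D0 <- Dg[24]; T20 <- Tg[20]
  ds <- small_dataset(data.frame(amplitude = 1, D = D0, T2 = T20))
  map <- ilt2d(ds, Dg, Tg, reg_weight = 1e-6)
  total <- sum(map$amplitude)
  expect_equal(total, 1, tolerance = 0.02)  # mass = extrapolated S(0,0)
  # the maximum sits on the true cell; the quadratic penalty spreads the
  # remaining mass only over strongly correlated neighbouring cells
  idx <- which(map$amplitude == max(map$amplitude), arr.ind = TRUE)[1, ]
  expect_lte(abs(idx[["row"]] - 24), 1)
  expect_lte(abs(idx[["col"]] - 20), 1)
  expect_gt(sum(map$amplitude[21:27, 17:23]) / total, 0.95)
})

test_that("the water peak is the highest-diffusivity component", {
  ds <- small_dataset(data.frame(amplitude = c(0.3, 0.7),
                                 D = c(9e-10, 4e-12), T2 = c(0.4, 0.12)),
                      n_echo = 64L)
  map <- ilt2d(ds, log_grid(1e-13, 1e-8, 48), log_grid(1e-3, 3, 48),
               reg_weight = 1e-5)
  expect_gte(nrow(map$peaks), 2)
  wp <- extract_water_peak(map)
  expect_equal(log10(wp$D), log10(9e-10), tolerance = 0.15)
  expect_equal(wp$mass, 0.3, tolerance = 0.1)
})

test_that("equal-diffusivity peaks tie-break deterministically by mass", {
  ds <- small_dataset(data.frame(amplitude = 1, D = 9e-10, T2 = 0.4))
  map <- ilt2d(ds, log_grid(1e-13, 1e-8, 32), log_grid(1e-3, 3, 32),
               reg_weight = 1e-5)
  # two synthetic regions in the same D row with different masses
  A <- matrix(0, 32, 32)
  A[20, 8] <- 1; A[20, 24] <- 2
  map$amplitude <- A
  map$peaks <- NULL
  wp <- extract_water_peak(map)
  expect_equal(wp$T2, map$T2_grid[24], tolerance = 1e-12)
  expect_equal(wp$mass, 2)
  map$amplitude <- matrix(0, 32, 32)
  map$peaks <- NULL
  expect_error(extract_water_peak(map), "no peak")
})

test_that("SVD-compressed and uncompressed solves agree", {
  Dg <- log_grid(1e-12, 1e-9, 8)
  Tg <- log_grid(5e-3, 1, 8)
  ds <- small_dataset(data.frame(amplitude = c(0.5, 0.5),
                                 D = c(Dg[6], Dg[3]), T2 = c(Tg[6], Tg[3])),
                      n_echo = 16L)
  lam <- 1  # strongly convex instance so both solves reach the optimum
  compressed <- ilt2d(ds, Dg, Tg, reg_weight = lam, sv_tol = 1e-7)
  full <- ilt2d(ds, Dg, Tg, reg_weight = lam, sv_tol = 1e-16)
  expect_lt(max(abs(compressed$amplitude - full$amplitude)), 1e-6)
})

test_that("the solve is invariant under row/column permutation", {
  Dg <- log_grid(1e-12, 1e-9, 8); Tg <- log_grid(5e-3, 1, 8)
  ds <- small_dataset(data.frame(amplitude = 1, D = Dg[5], T2 = Tg[4]),
                      n_echo = 12L)
  ker <- build_kernels(ds, Dg, Tg)
  F1 <- emulsionrheo:::.nn_tikhonov(ker$K1, ker$K2, ds$signal, 1)
  ig <- rev(seq_len(nrow(ker$K1)))
  it <- withr::with_seed(21, sample(seq_len(nrow(ker$K2))))
  F2 <- emulsionrheo:::.nn_tikhonov(ker$K1[ig, ], ker$K2[it, ],
                                    ds$signal[ig, it], 1)
  expect_lt(max(abs(F1 - F2)) / max(F1), 1e-6)
})

test_that("stronger regularization spreads mass and lowers peaks", {
  Dg <- log_grid(1e-12, 1e-9, 16); Tg <- log_grid(5e-3, 1, 16)
  ds <- small_dataset(data.frame(amplitude = 1, D = Dg[10], T2 = Tg[8]),
                      n_echo = 16L)
  peaks <- vapply(c(1e-6, 1e-3, 1, 1e3), function(lam)
    max(ilt2d(ds, Dg, Tg, reg_weight = lam)$amplitude), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("auto regularization satisfies the discrepancy principle", {
  ds <- small_dataset(data.frame(amplitude = c(0.3, 0.7),
                                 D = c(9e-10, 4e-12), T2 = c(0.4, 0.12)),
                      noise = noise_spec(2e-3, 31, "additive"),
                      n_echo = 64L)
  map <- ilt2d(ds, log_grid(1e-13, 1e-8, 32), log_grid(1e-3, 3, 32))
  noise_norm <- 2e-3 * sqrt(length(ds$signal))
  expect_lt(map$residual_norm, 2 * noise_norm)
})

test_that("degenerate datasets are handled explicitly", {
  ds <- small_dataset(data.frame(amplitude = 1, D = 9e-10, T2 = 0.4))
  ds$signal[] <- 0
  map <- ilt2d(ds)
  expect_identical(sum(map$amplitude), 0)
  expect_identical(nrow(map$peaks), 0L)
})

test_that("T2-versus-concentration calibration is ordinary least squares", {
  conc <- c(1, 2, 3, 4)
  cal <- t2_concentration_fit(conc, 500 - 30 * conc)
  expect_equal(cal$slope, -30, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-10)
  flat <- t2_concentration_fit(conc, rep(400, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(t2_concentration_fit(c(1, 2), c(3, 4)), "at least 3")
  withr::with_seed(6, {
    y <- 500 - 30 * conc + rnorm(4, 0, 2)
    noisy <- t2_concentration_fit(conc, y)
    se <- summary(stats::lm(y ~ conc))$coefficients[2, 2]
    expect_lt(abs(noisy$slope - (-30)), 3 * se)
  })
})

test_that("diffusion length follows the square-root law", {
  expect_equal(diffusion_length(9e-10, 0.2) * 1e6, 18.97, tolerance = 1e-3)
  expect_identical(diffusion_length(9e-10, 0), 0)
  expect_equal(diffusion_length(9e-10, 0.8) / diffusion_length(9e-10, 0.2),
               2)
})
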