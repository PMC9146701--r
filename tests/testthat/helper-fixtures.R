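# Shared fixtures: the default cell, a mid-strength Herschel-Bulkley law,
# and generators used across test files.

default_geom <- couette_geometry()

# a local flow curve sampled from the HB law over about a decade of
# shear rate, optionally with seeded multiplicative stress noise
law_lfc <- function(tau0, K = 30, n = 0.47,
                    gamma_dot = exp(seq(log(0.5), log(20),
                                        length.out = 20)),
                    noise = NULL, time_stamp = NA_real_) {
  sigma <- apply_noise(hb_stress(hb_params(tau0, K, n), gamma_dot), noise)
  local_flow_curve(gamma_dot, sigma, time_stamp = time_stamp)
}

# six-curve time series with tau0 decaying along the structural kinetics
law_lfc_series <- function(n = 0.47, K = 30, sigma_noise = 0, seed = 1,
                           times = c(0, 30, 90, 180, 330, 500),
                           skm = skm_params(80.1, 44, 0.012)) {
  tau0s <- skm_model(skm, times)
  lapply(seq_along(times), function(i) {
    ns <- if (sigma_noise > 0)
      noise_spec(sigma_noise, seed * 1000L + i, "multiplicative") else NULL
    law_lfc(tau0s[i], K, n, noise = ns, time_stamp = times[i])
  })
}

# brute-force Savitzky-Golay oracle: an explicit least-squares polynomial
# fit in each (one-sided at the edges) window, differentiated analytically
polyfit_derivative <- function(values, positions, window, poly_order) {
  N <- length(values)
  half <- (window - 1) %/% 2
  vapply(seq_len(N), function(i) {
    j <- max(1, min(i - half, N - window + 1))
    idx <- j:(j + window - 1)
    co <- stats::coef(stats::lm(values[idx] ~
                                  stats::poly(positions[idx], poly_order,
                                              raw = TRUE)))
    sum(vapply(seq_len(poly_order), function(k)
      k * co[k + 1] * positions[i]^(k - 1), 0))
  }, numeric(1))
}

minispec_pgse <- pgse_params(seq(0.1, 3, length.out = 32),
                             delta = 2e-3, Delta = 211e-3)

dt2_pgse <- pgse_params(seq(0.1, 6.6, length.out = 32),
                        delta = 1e-3, Delta = 200e-3)
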