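#' Rheo-MRI velocity profile
#'
#' One azimuthal velocity profile across the Couette gap, as tabulated from
#' a velocity-encoded MRI measurement: radial positions (strictly
#' ascending), velocities, an optional time stamp and the nominal applied
#' shear rate.  At least 7 points are required so that the default
#' Savitzky-Golay differentiation window fits.
#'
#' @param r Radial positions in metres, strictly ascending.
#' @param v Azimuthal velocities in m/s, same length as `r`.
#' @param time_stamp Acquisition time (in the pipeline's time unit,
#'   typically minutes of shearing); `NA` if untimed.
#' @param applied_rate Nominal applied shear rate in 1/s; `NA` if unknown.
#' @return An object of class `velocity_profile`.
#' @export
velocity_profile <- function(r, v, time_stamp = NA_real_,
                             applied_rate = NA_real_) {
  stopifnot(is.numeric(r), is.numeric(v))
  if (length(r) != length(v))
    stop("r and v must have the same length", call. = FALSE)
  if (length(r) < 7L)
    stop("a velocity profile needs at least 7 points", call. = FALSE)
  if (any(diff(r) <= 0))
    stop("radial positions must be strictly ascending", call. = FALSE)
  structure(list(r = as.numeric(r), v = as.numeric(v),
                 time_stamp = time_stamp, applied_rate = applied_rate),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf(
    "Velocity profile: %d points, r in [%.4g, %.4g] mm, max |v| = %.4g mm/s\n",
    length(x$r), min(x$r) * 1e3, max(x$r) * 1e3, max(abs(x$v)) * 1e3))
  invisible(x)
}

#' Add seeded noise to a velocity profile
#'
#' @param profile A [velocity_profile()].
#' @param noise A [noise_spec()]; additive sigma is in m/s.
#' @return A new `velocity_profile` with perturbed velocities.
#' @export
noisy_profile <- function(profile, noise) {
  stopifnot(inherits(profile, "velocity_profile"))
  velocity_profile(profile$r, apply_noise(profile$v, noise),
                   time_stamp = profile$time_stamp,
                   applied_rate = profile$applied_rate)
}

#' Savitzky-Golay first derivative on a uniform grid
#'
#' Least-squares local-polynomial differentiation: at each point a
#' polynomial of order `poly_order` is fitted over a `window`-point
#' neighbourhood and its first derivative evaluated.  Interior points use
#' the centred window; the first and last `(window-1)/2` points use
#' one-sided fits of the same order, so the full gap keeps coverage instead
#' of being truncated.  Filter coefficients come from [signal::sgolay()],
#' whose transient rows are exactly these one-sided fits.
#'
#' @param values Sampled function values.
#' @param positions Sample positions; must be uniformly spaced (relative
#'   tolerance 1e-6).
#' @param window Odd window length, `<= length(values)`.
#' @param poly_order Polynomial order, `< window`.
#' @return Derivative estimates at each position.
#' @examples
#' x <- seq(0, 1, length.out = 21)
#' sg_derivative(3 * x + 2, x)  # ~3 everywhere
#' @export
sg_derivative <- function(values, positions, window = 7L, poly_order = 1L) {
  stopifnot(is.numeric(values), is.numeric(positions),
            length(values) == length(positions))
  n <- as.integer(window); p <- as.integer(poly_order)
  if (n %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (n > length(values))
    stop("window exceeds the number of points", call. = FALSE)
  if (p >= n) stop("poly_order must be smaller than window", call. = FALSE)
  h <- diff(positions)
  if (any(h <= 0) || max(abs(h - mean(h))) > 1e-6 * mean(abs(h)))
    stop("positions must be uniformly spaced; resample the profile first",
         call. = FALSE)
  h <- mean(h)
  FF <- unclass(signal::sgolay(p = p, n = n, m = 1))
  N <- length(values); half <- (n - 1L) %/% 2L
  d <- numeric(N)
  for (i in seq_len(N)) {
    if (i <= half) {
      d[i] <- sum(FF[i, ] * values[1:n])
    } else if (i > N - half) {
      d[i] <- sum(FF[n - (N - i), ] * values[(N - n + 1L):N])
    } else {
      d[i] <- sum(FF[half + 1L, ] * values[(i - half):(i + half)])
    }
  }
  d / h
}

#' Local shear rate across the gap from a velocity profile
#'
#' For azimuthal Couette flow the deformation rate is
#' gamma_dot(r) = | r d(v/r)/dr |.  The ratio v/r (the angular velocity) is
#' formed first and differentiated in a single Savitzky-Golay pass, which
#' avoids amplifying noise through two separate numerical steps and makes
#' rigid-body rotation map exactly to zero shear.
#'
#' @param profile A [velocity_profile()].
#' @param window,poly_order Savitzky-Golay settings; the defaults (7-point
#'   window, first-order polynomial) match common rheo-MRI practice.
#' @return Non-negative shear rates (1/s) at each radial position.
#' @export
shear_rate_profile <- function(profile, window = 7L, poly_order = 1L) {
  stopifnot(inherits(profile, "velocity_profile"))
  if (any(profile$r <= 0))
    stop("radial positions must be positive inside a Couette gap",
         call. = FALSE)
  omega <- profile$v / profile$r
  abs(profile$r * sg_derivative(omega, profile$r, window, poly_order))
}

#' Local flow curve
#'
#' Paired (shear rate, stress) samples across the gap at one time point:
#' the central intermediate of the pipeline.  Stress must be strictly
#' decreasing with radius (it is sigma = T / (2 pi r^2 H) by construction);
#' `r` may be omitted for law-generated curves that carry no positions.
#'
#' @param gamma_dot Shear rates in 1/s (>= 0).
#' @param sigma Stresses in Pa.
#' @param r Radial positions in metres (optional).
#' @param time_stamp Shearing time of the measurement.
#' @return An object of class `local_flow_curve`.
#' @export
local_flow_curve <- function(gamma_dot, sigma, r = NULL,
                             time_stamp = NA_real_) {
  stopifnot(is.numeric(gamma_dot), is.numeric(sigma))
  if (length(gamma_dot) != length(sigma))
    stop("gamma_dot and sigma must have the same length", call. = FALSE)
  if (any(gamma_dot < 0))
    stop("shear rates must be non-negative", call. = FALSE)
  if (!is.null(r)) {
    if (length(r) != length(sigma))
      stop("r must match the number of samples", call. = FALSE)
    if (length(r) > 1L) {
      ord <- order(r)
      if (any(diff(sigma[ord]) >= 0))
        stop("stress must be strictly decreasing with radius", call. = FALSE)
    }
  }
  structure(list(gamma_dot = as.numeric(gamma_dot),
                 sigma = as.numeric(sigma),
                 r = if (is.null(r)) NULL else as.numeric(r),
                 time_stamp = time_stamp),
            class = "local_flow_curve")
}

#' @export
print.local_flow_curve <- function(x, ...) {
  cat(sprintf(
    "Local flow curve: %d points, gamma_dot in [%.3g, %.3g] 1/s, sigma in [%.4g, %.4g] Pa\n",
    length(x$gamma_dot),
    if (length(x$gamma_dot)) min(x$gamma_dot) else NA,
    if (length(x$gamma_dot)) max(x$gamma_dot) else NA,
    if (length(x$sigma)) min(x$sigma) else NA,
    if (length(x$sigma)) max(x$sigma) else NA))
  invisible(x)
}

#' Assemble a local flow curve from a velocity profile and torque
#'
#' Combines the Savitzky-Golay shear-rate profile with the torque-derived
#' stress profile into pointwise (gamma_dot, sigma) pairs.  Positions whose
#' reconstructed shear rate falls below `mask_threshold` are excluded: below
#' the velocimetry noise floor the shear rate is not resolvable, and in a
#' partially yielded gap the region beyond the yield radius carries no flow
#' information.
#'
#' By default the `(window - 1)/2` near-wall points on each side are also
#' excluded.  Their shear rates come from one-sided polynomial fits whose
#' first-order bias scales with the window span times the profile
#' curvature — several percent at typical rheo-MRI resolution — which
#' would contaminate the flow curve; set `mask_edges = FALSE` to keep the
#' full gap coverage that [sg_derivative()] provides.
#'
#' @param profile A [velocity_profile()].
#' @param torque Concurrent torque reading in N m.
#' @param geometry A [couette_geometry()].
#' @param mask_threshold Minimum resolvable shear rate in 1/s (default
#'   0.05); set to 0 to keep every position.
#' @param mask_edges Exclude the one-sided (transient) Savitzky-Golay
#'   points near the walls (default `TRUE`).
#' @param window,poly_order Savitzky-Golay settings passed on to
#'   [shear_rate_profile()].
#' @param torque_time Optional time stamp of the torque reading; if given,
#'   it must match the profile time stamp within `time_tolerance`.
#' @param time_tolerance Pairing tolerance for the two time stamps.
#' @return A [local_flow_curve()]; may be empty if everything is masked.
#' @export
assemble_lfc <- function(profile, torque, geometry, mask_threshold = 0.05,
                         mask_edges = TRUE, window = 7L, poly_order = 1L,
                         torque_time = NULL, time_tolerance = 1e-6) {
  stopifnot(inherits(profile, "velocity_profile"),
            inherits(geometry, "couette_geometry"))
  if (!is.null(torque_time) && is.finite(profile$time_stamp) &&
      abs(torque_time - profile$time_stamp) > time_tolerance)
    stop(sprintf(
      "torque time stamp (%g) does not match profile time stamp (%g)",
      torque_time, profile$time_stamp), call. = FALSE)
  gdot <- shear_rate_profile(profile, window, poly_order)
  sigma <- stress_profile(torque, geometry, profile$r)
  keep <- gdot >= mask_threshold
  if (mask_edges) {
    half <- (as.integer(window) - 1L) %/% 2L
    n <- length(gdot)
    keep[c(seq_len(half), (n - half + 1L):n)] <- FALSE
  }
  local_flow_curve(gdot[keep], sigma[keep], r = profile$r[keep],
                   time_stamp = profile$time_stamp)
}
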