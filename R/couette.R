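#' Rotor rate corresponding to a nominal applied shear rate
#'
#' Narrow-gap convention: Omega = gamma_dot_applied * (Ro - Ri) / Ri, i.e.
#' the rate at which a rheometer reports "applied shear rate" for a thin
#' concentric-cylinder gap.
#'
#' @param applied_rate Nominal applied shear rate in 1/s.
#' @param geometry A [couette_geometry()].
#' @return Rotor angular velocity in rad/s.
#' @export
rotor_rate_from_applied <- function(applied_rate, geometry) {
  stopifnot(inherits(geometry, "couette_geometry"), applied_rate >= 0)
  applied_rate * geometry$gap / geometry$inner_radius
}

#' Forward-solve steady Couette flow of a Herschel-Bulkley fluid
#'
#' Computes the steady azimuthal flow of a Herschel-Bulkley fluid in a
#' narrow-gap Couette cell with the inner cylinder rotating at `rotor_rate`
#' and the outer cylinder fixed.  The stress field is fixed by the torque,
#' sigma(r) = T / (2 pi r^2 H); the local shear rate follows from the
#' constitutive law, gamma_dot(r) = ((sigma(r) - tau0) / K)^(1/n) where the
#' material is yielded and zero beyond the yield radius.  The torque is
#' found by root-bracketing on the kinematic constraint
#' Omega = integral of gamma_dot(r)/r from Ri to min(ry, Ro).
#'
#' When the applied rate is too low to yield the whole gap the flow
#' localizes: velocity vanishes for r beyond the yield radius
#' ry = sqrt(T / (2 pi H tau0)), the shear-banding signature seen in
#' yield-stress fluids imaged across a Couette gap.
#'
#' @param geometry A [couette_geometry()].
#' @param hb An [hb_params()] constitutive law.
#' @param rotor_rate Inner-cylinder angular velocity in rad/s (>= 0).
#' @param r Radial sample positions (m); default a 48.8 um grid across the
#'   gap, matching a typical rheo-MRI voxel size.
#' @param rel_tol Relative tolerance of the quadrature and torque root.
#'
#' @return An object of class `couette_solution`: list with `profile`
#'   (a [velocity_profile()]), `torque` (N m), `yield_radius` (m, `NA` when
#'   the whole gap is yielded) and `fully_yielded` flag.
#' @examples
#' geom <- couette_geometry()
#' sol <- couette_forward_solve(geom, hb_params(50, 30, 0.47),
#'                              rotor_rate_from_applied(5, geom))
#' sol$torque
#' @export
couette_forward_solve <- function(geometry, hb, rotor_rate,
                                  r = NULL, rel_tol = 1e-10) {
  stopifnot(inherits(geometry, "couette_geometry"), inherits(hb, "hb_params"))
  if (!is.numeric(rotor_rate) || length(rotor_rate) != 1L || rotor_rate < 0)
    stop("rotor_rate must be a single non-negative number", call. = FALSE)
  Ri <- geometry$inner_radius; Ro <- geometry$outer_radius
  H <- geometry$height
  if (is.null(r)) {
    dr <- 48.8e-6
    r <- seq(Ri, Ri + floor(geometry$gap / dr) * dr, by = dr)
  }
  tol <- 1e-9 * geometry$gap
  if (any(r < Ri - tol | r > Ro + tol))
    stop("sample positions must lie inside the gap", call. = FALSE)
  applied <- rotor_rate * Ri / geometry$gap

  if (rotor_rate == 0) {
    profile <- velocity_profile(r, rep(0, length(r)), applied_rate = 0)
    return(structure(
      list(profile = profile, torque = 2 * pi * Ri^2 * H * hb$tau0,
           yield_radius = if (hb$tau0 > 0) Ri else NA_real_,
           fully_yielded = hb$tau0 == 0, at_yield_boundary = TRUE),
      class = "couette_solution"))
  }

  gdot_at <- function(s, torque) {
    sigma <- torque / (2 * pi * s^2 * H)
    ifelse(sigma > hb$tau0, ((sigma - hb$tau0) / hb$K)^(1 / hb$n), 0)
  }
  yield_r <- function(torque) {
    if (hb$tau0 == 0) Inf else sqrt(torque / (2 * pi * H * hb$tau0))
  }
  omega_of <- function(torque) {
    up <- min(yield_r(torque), Ro)
    if (up <= Ri) return(0)
    stats::integrate(function(s) gdot_at(s, torque) / s, Ri, up,
                     rel.tol = rel_tol, abs.tol = 0)$value
  }

  # bracket the torque: below T_yield the gap does not move at all
  t_lo <- 2 * pi * Ri^2 * H * hb$tau0
  t_hi <- max(t_lo, 2 * pi * Ri^2 * H *
                (hb$tau0 + hb$K * (rotor_rate * Ri / geometry$gap)^hb$n))
  it <- 0
  while (omega_of(t_hi) < rotor_rate) {
    t_hi <- t_hi * 2
    it <- it + 1
    if (it > 200)
      stop(sprintf(
        "torque root search failed to bracket: Omega(%.3g N.m) = %.3g < %.3g rad/s",
        t_hi, omega_of(t_hi), rotor_rate), call. = FALSE)
  }
  torque <- stats::uniroot(function(t) omega_of(t) - rotor_rate,
                           lower = t_lo, upper = t_hi,
                           tol = max(1e-18, rel_tol * t_hi))$root

  ry <- yield_r(torque)
  up <- min(ry, Ro)
  omega_r <- vapply(r, function(ri) {
    if (ri >= up) return(0)
    stats::integrate(function(s) gdot_at(s, torque) / s, ri, up,
                     rel.tol = rel_tol, abs.tol = 0)$value
  }, numeric(1))
  profile <- velocity_profile(r, r * omega_r, applied_rate = applied)
  structure(
    list(profile = profile, torque = torque,
         yield_radius = if (ry < Ro) ry else NA_real_,
         fully_yielded = ry >= Ro, at_yield_boundary = FALSE),
    class = "couette_solution")
}

#' @export
print.couette_solution <- function(x, ...) {
  cat(sprintf("Couette solution: torque %.4g N.m, %s\n", x$torque,
              if (x$fully_yielded) "fully yielded gap"
              else sprintf("shear localization, yield radius %.4g mm",
                           x$yield_radius * 1e3)))
  invisible(x)
}
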