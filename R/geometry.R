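#' Concentric-cylinder (Couette) cell geometry
#'
#' Describes the narrow-gap Couette cell used for rheo-MRI velocimetry and
#' for the concurrent torque measurement.  Defaults correspond to a cell
#' with 20 mm / 22 mm inner and outer diameters (1 mm gap); the cell height
#' enters only through the torque-to-stress conversion and is configurable.
#'
#' @param inner_radius Inner (rotating) cylinder radius in metres.
#' @param outer_radius Outer (fixed) cylinder radius in metres.
#' @param height Cell height in metres.
#'
#' @return An object of class `couette_geometry` with fields
#'   `inner_radius`, `outer_radius`, `height` and the derived `gap`.
#' @examples
#' geom <- couette_geometry()
#' geom$gap  # 1 mm
#' @export
couette_geometry <- function(inner_radius = 10e-3,
                             outer_radius = 11e-3,
                             height = 40e-3) {
  stopifnot(is.numeric(inner_radius), is.numeric(outer_radius),
            is.numeric(height), length(inner_radius) == 1L,
            length(outer_radius) == 1L, length(height) == 1L)
  if (!(inner_radius > 0 && outer_radius > inner_radius))
    stop("need 0 < inner_radius < outer_radius", call. = FALSE)
  if (height <= 0) stop("height must be positive", call. = FALSE)
  structure(
    list(inner_radius = inner_radius, outer_radius = outer_radius,
         height = height, gap = outer_radius - inner_radius),
    class = "couette_geometry"
  )
}

#' @export
print.couette_geometry <- function(x, ...) {
  cat(sprintf("Couette cell: Ri = %.3f mm, Ro = %.3f mm (gap %.3f mm), H = %.1f mm\n",
              x$inner_radius * 1e3, x$outer_radius * 1e3, x$gap * 1e3,
              x$height * 1e3))
  invisible(x)
}

#' Herschel-Bulkley constitutive parameters
#'
#' The Herschel-Bulkley law sigma = tau0 + K * gamma_dot^n combines a yield
#' stress `tau0` with a power-law viscous stress of consistency `K` and flow
#' index `n`.
#'
#' @param tau0 Yield stress in Pa (>= 0).
#' @param K Consistency in Pa s^n (> 0).
#' @param n Flow index, dimensionless, in (0, 2].
#'
#' @return An object of class `hb_params`.
#' @examples
#' hb_params(tau0 = 80, K = 30, n = 0.47)
#' @export
hb_params <- function(tau0, K, n) {
  stopifnot(is.numeric(tau0), is.numeric(K), is.numeric(n))
  if (tau0 < 0) stop("tau0 must be >= 0", call. = FALSE)
  if (K <= 0) stop("K must be > 0", call. = FALSE)
  if (n <= 0 || n > 2) stop("flow index n must lie in (0, 2]", call. = FALSE)
  structure(list(tau0 = tau0, K = K, n = n), class = "hb_params")
}

#' @export
print.hb_params <- function(x, ...) {
  cat(sprintf("Herschel-Bulkley: tau0 = %.4g Pa, K = %.4g Pa.s^n, n = %.4g\n",
              x$tau0, x$K, x$n))
  invisible(x)
}

#' Evaluate the Herschel-Bulkley stress
#'
#' @param hb An [hb_params()] object.
#' @param gamma_dot Shear rates in 1/s (>= 0).
#' @return Stresses in Pa.
#' @export
hb_stress <- function(hb, gamma_dot) {
  stopifnot(inherits(hb, "hb_params"), all(gamma_dot >= 0))
  hb$tau0 + hb$K * gamma_dot^hb$n
}

#' Local stress across a Couette gap from measured torque
#'
#' In a concentric-cylinder cell the momentum balance fixes the stress at
#' radius r from the measured torque T as sigma(r) = T / (2 pi r^2 H), with
#' H the cell height.  The stress therefore decreases as 1/r^2 across the
#' gap for any positive torque.
#'
#' @param torque Measured torque in N m (>= 0).
#' @param geometry A [couette_geometry()].
#' @param r Radial positions in metres, all inside `[Ri, Ro]`.
#' @return Stresses sigma(r) in Pa.
#' @examples
#' geom <- couette_geometry(height = 50e-3)
#' stress_profile(1e-3, geom, 10.5e-3)  # ~28.87 Pa
#' @export
stress_profile <- function(torque, geometry, r) {
  stopifnot(inherits(geometry, "couette_geometry"))
  if (!is.numeric(torque) || length(torque) != 1L || torque < 0)
    stop("torque must be a single non-negative number", call. = FALSE)
  tol <- 1e-9 * geometry$gap
  if (any(r < geometry$inner_radius - tol | r > geometry$outer_radius + tol))
    stop("radial positions must lie inside the gap [Ri, Ro]", call. = FALSE)
  torque / (2 * pi * r^2 * geometry$height)
}
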