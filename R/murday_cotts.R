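# Roots x_m of the sphere reflecting-boundary condition for the radial
# eigenmodes of diffusion, x J'_{3/2}(x) - (1/2) J_{3/2}(x) = 0, which
# reduces to (x^2 - 2) sin x + 2 x cos x = 0 (the stationary points of the
# spherical Bessel function j1).  alpha_m = x_m / R.
.root_cache <- new.env(parent = emptyenv())

#' Positive roots of the sphere-boundary eigenvalue condition
#'
#' @param n_roots Number of roots wanted.
#' @return The first `n_roots` positive roots (dimensionless, i.e.
#'   `alpha_m * R`); the first is 2.08158...
#' @export
sphere_bessel_roots <- function(n_roots = 50L) {
  n_roots <- as.integer(n_roots)
  stopifnot(n_roots >= 1L)
  have <- get0("roots", envir = .root_cache, ifnotfound = numeric(0))
  if (length(have) >= n_roots) return(have[seq_len(n_roots)])
  f <- function(x) (x^2 - 2) * sin(x) + 2 * x * cos(x)
  roots <- have
  a <- if (length(roots)) roots[length(roots)] + 0.25 else 0.5
  while (length(roots) < n_roots) {
    b <- a + 0.5
    if (f(a) * f(b) < 0)
      roots <- c(roots, stats::uniroot(f, c(a, b), tol = 1e-14)$root)
    a <- b
  }
  assign("roots", roots, envir = .root_cache)
  roots[seq_len(n_roots)]
}

# Attenuation exponent per unit g^2: ln E = psi * g^2.  Gaussian phase
# approximation for diffusion restricted inside a sphere of radius R.
# When max_roots > n_roots the truncation is grown geometrically until the
# tail bound passes; spheres far beyond the diffusion length short-circuit
# to the free-diffusion exponent (series and limit agree to ~2e-5 there).
.mc_psi <- function(radius, diffusivity, pgse, n_roots,
                    max_roots = n_roots) {
  d <- pgse$delta; D <- pgse$Delta
  if (radius >= 300 * sqrt(diffusivity * D))
    return(-pgse$gamma^2 * d^2 * diffusivity * (D - d / 3))
  nr <- n_roots
  repeat {
    x <- sphere_bessel_roots(nr)
    am <- x / radius
    a2D <- am^2 * diffusivity
    # algebraically num = 2d - (2 + e^{-a(D-d)} - 2e^{-ad} - 2e^{-aD}
    #                          + e^{-a(D+d)})/a, but that cancels
    # catastrophically when a*D << 1 (large spheres); the expm1 form
    # below is exact and stable in both regimes
    num <- (2 * d + 2 * expm1(-a2D * d) / a2D) -
      (exp(-a2D * (D - d) / 2) - exp(-a2D * (D + d) / 2))^2 / a2D
    terms <- num / (am^4 * (am^2 * radius^2 - 2))
    s <- sum(terms)
    # terms fall off like x^-6; bound the dropped tail by its integral
    tail_est <- abs(terms[length(terms)]) * x[length(x)] / (5 * pi)
    if (tail_est <= 1e-5 * abs(s)) break
    if (nr >= max_roots)
      stop(sprintf(
        "Murday-Cotts series not converged with %d roots; increase n_roots",
        nr), call. = FALSE)
    nr <- min(2L * nr, max_roots)
  }
  -2 * pgse$gamma^2 * s / diffusivity
}

#' PGSE attenuation for diffusion restricted inside a sphere
#'
#' Gaussian-phase-approximation (Murday-Cotts) echo attenuation of
#' molecules diffusing inside a sphere of radius `radius` with bulk
#' diffusivity `diffusivity`, for each gradient strength of the
#' acquisition.  The eigenmode series is truncated at `n_roots` terms and a
#' convergence check on the last retained term raises an error naming the
#' truncation if it is too short.
#'
#' Limiting behaviour: for spheres much larger than the diffusion length
#' the result approaches the free-diffusion Stejskal-Tanner form
#' exp(-b(g) D); for spheres much smaller than sqrt(D delta) the motion is
#' fully averaged and E -> 1.
#'
#' @param radius Sphere radius in metres (> 0).
#' @param diffusivity Bulk self-diffusivity in m^2/s (> 0).
#' @param pgse A [pgse_params()].
#' @param n_roots Series truncation (default 50).
#' @return Attenuations E in (0, 1], one per gradient strength; E = 1 at
#'   g = 0.
#' @examples
#' p <- pgse_params(c(0, 1, 2), delta = 2e-3, Delta = 211e-3)
#' murday_cotts_attenuation(1.7e-6, 4e-12, p)
#' @export
murday_cotts_attenuation <- function(radius, diffusivity, pgse,
                                     n_roots = 50L) {
  stopifnot(inherits(pgse, "pgse_params"))
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (diffusivity <= 0) stop("diffusivity must be > 0", call. = FALSE)
  psi <- .mc_psi(radius, diffusivity, pgse, n_roots)
  exp(psi * pgse$gradient_strengths^2)
}

#' PFG decay container
#'
#' @param gradient_strengths Gradient amplitudes in T/m, ascending.
#' @param attenuation Normalized echo attenuations E(g).
#' @return An object of class `pfg_decay`.
#' @export
pfg_decay <- function(gradient_strengths, attenuation) {
  stopifnot(is.numeric(gradient_strengths), is.numeric(attenuation),
            length(gradient_strengths) == length(attenuation))
  if (any(diff(gradient_strengths) <= 0))
    stop("gradient strengths must be strictly increasing", call. = FALSE)
  if (any(attenuation <= 0))
    stop("attenuations must be positive", call. = FALSE)
  structure(list(gradient_strengths = as.numeric(gradient_strengths),
                 attenuation = as.numeric(attenuation)),
            class = "pfg_decay")
}

#' @export
print.pfg_decay <- function(x, ...) {
  cat(sprintf("PFG decay: %d gradient steps, E in [%.3g, %.3g]\n",
              length(x$gradient_strengths), min(x$attenuation),
              max(x$attenuation)))
  invisible(x)
}

#' PFG decay of a lognormal droplet-size distribution
#'
#' Volume-weighted average of the single-sphere Murday-Cotts attenuation
#' over a lognormal distribution of droplet diameters.  The distribution is
#' parameterized the way emulsion droplet sizing reports it: `D33` is the
#' median of the volume-weighted diameter distribution in micrometres and
#' `alpha` its log-domain width (dimensionless).  The average is taken by
#' Gauss-Legendre quadrature over +/- 4 alpha in log diameter.
#'
#' @param D33 Volume-weighted median droplet diameter in micrometres (> 0).
#' @param alpha Lognormal width (log-std); `alpha = 0` degenerates to a
#'   single sphere of diameter `D33`.
#' @param D_oil Self-diffusivity of the dispersed (oil) phase in m^2/s.
#' @param pgse A [pgse_params()].
#' @param quadrature_nodes Gauss-Legendre node count (default 64).
#' @param n_roots Murday-Cotts series truncation.
#' @param noise Optional [noise_spec()] applied to the attenuations.
#' @return A [pfg_decay()].
#' @examples
#' p <- pgse_params(seq(0.1, 3, length.out = 16), delta = 2e-3,
#'                  Delta = 211e-3)
#' pfg_decay_lognormal(3.39, 0.20, 4e-12, p)
#' @export
pfg_decay_lognormal <- function(D33, alpha, D_oil, pgse,
                                quadrature_nodes = 64L, n_roots = 50L,
                                noise = NULL) {
  stopifnot(inherits(pgse, "pgse_params"))
  if (D33 <= 0) stop("D33 must be > 0", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  g <- pgse$gradient_strengths
  mu <- log(D33 * 1e-6)  # log median diameter in metres
  if (alpha < 1e-8) {
    psi <- .mc_psi(exp(mu) / 2, D_oil, pgse, n_roots,
                   max_roots = max(4096L, n_roots))
    E <- exp(psi * g^2)
  } else {
    gl <- pracma::gaussLegendre(quadrature_nodes, mu - 4 * alpha,
                                mu + 4 * alpha)
    w <- gl$w * stats::dnorm(gl$x, mu, alpha)
    w <- w / sum(w)
    E <- rep(0, length(g))
    for (i in seq_along(gl$x)) {
      psi <- .mc_psi(exp(gl$x[i]) / 2, D_oil, pgse, n_roots,
                     max_roots = max(4096L, n_roots))
      E <- E + w[i] * exp(psi * g^2)
    }
    E[g == 0] <- 1  # exact: the quadrature weights sum to 1
  }
  pfg_decay(g, apply_noise(E, noise))
}
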