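#' Droplet-size distribution fitted from a PFG decay
#'
#' Container for the volume-weighted lognormal droplet-size distribution:
#' median diameter `D33` (micrometres), log-domain width `alpha`, the oil
#' self-diffusivity used (or fitted), fit residual, uncertainties and
#' flags.
#'
#' @keywords internal
droplet_size_distribution <- function(D33, alpha, D_oil, se,
                                      fit_residual, flags = character(0)) {
  stopifnot(D33 > 0, alpha >= 0)
  structure(list(D33 = D33, alpha = alpha, D_oil = D_oil, se = se,
                 fit_residual = fit_residual, flags = flags),
            class = "droplet_size_distribution")
}

#' @export
print.droplet_size_distribution <- function(x, ...) {
  cat(sprintf(
    "Droplet size: D3,3 = %.4g +/- %.2g um, alpha = %.3g +/- %.2g (D_oil = %.3g m^2/s)%s\n",
    x$D33, x$se["D33"], x$alpha, x$se["alpha"], x$D_oil,
    if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' Fit a lognormal droplet-size distribution to a PFG decay
#'
#' Least-squares inversion of a pulsed-field-gradient attenuation decay
#' through the Murday-Cotts restricted-diffusion forward model averaged
#' over a volume-weighted lognormal diameter distribution
#' ([pfg_decay_lognormal()]).  Fitted parameters are the median diameter
#' `D33` (bounded to 0.1-100 um) and width `alpha` (bounded to 0-2); the
#' oil self-diffusivity is fixed by default because a joint
#' (D33, alpha, D_oil) fit is weakly identified at typical 32-step gradient
#' tables, but can be freed.
#'
#' @param decay A [pfg_decay()] with >= 6 gradient points and attenuation
#'   reaching below 0.7 (otherwise the decay carries too little size
#'   information and an "under-encoded" error is raised).
#' @param pgse The [pgse_params()] of the acquisition.
#' @param D_oil Oil self-diffusivity in m^2/s (default 4e-12, typical of
#'   vegetable oil at room temperature).
#' @param fit_D_oil Also fit `D_oil` (bounded 1e-13 to 1e-10 m^2/s).
#' @param quadrature_nodes,n_roots Forward-model settings.
#' @return A `droplet_size_distribution`.
#' @examples
#' p <- pgse_params(seq(0.1, 3, length.out = 32), delta = 2e-3,
#'                  Delta = 211e-3)
#' dec <- pfg_decay_lognormal(3.39, 0.20, 4e-12, p)
#' fit_droplet_size(dec, p)
#' @export
fit_droplet_size <- function(decay, pgse, D_oil = 4e-12, fit_D_oil = FALSE,
                             quadrature_nodes = 64L, n_roots = 50L) {
  stopifnot(inherits(decay, "pfg_decay"), inherits(pgse, "pgse_params"))
  g <- decay$gradient_strengths; E <- decay$attenuation
  if (length(g) < 6L)
    stop("at least 6 gradient points are required", call. = FALSE)
  if (min(E) >= 0.7)
    stop("under-encoded decay: attenuation never falls below 0.7, droplet size is not constrained",
         call. = FALSE)
  if (!isTRUE(all.equal(g, pgse$gradient_strengths, tolerance = 1e-8)))
    stop("decay gradient table does not match the PGSE parameters",
         call. = FALSE)

  model <- function(D33, alpha, Do) {
    pfg_decay_lognormal(D33, max(alpha, 0), Do, pgse,
                        quadrature_nodes = quadrature_nodes,
                        n_roots = n_roots)$attenuation
  }
  if (fit_D_oil) {
    par <- c(D33 = 3, alpha = 0.3, lDo = log(D_oil))
    fn <- function(p) model(p[["D33"]], p[["alpha"]], exp(p[["lDo"]])) - E
    lower <- c(0.1, 0, log(1e-13)); upper <- c(100, 2, log(1e-10))
  } else {
    par <- c(D33 = 3, alpha = 0.3)
    fn <- function(p) model(p[["D33"]], p[["alpha"]], D_oil) - E
    lower <- c(0.1, 0); upper <- c(100, 2)
  }
  starts <- list(par,
                 replace(par, "D33", 1),
                 replace(par, "D33", 10))
  best <- NULL
  for (s in starts) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = s, fn = fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300, maxfev = 100000, ftol = 1e-13,
                                           ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(f) || f$info %in% c(0, 9)) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best))
    stop("droplet-size fit failed to converge; starts tried: D33 = 3, 1, 10 um",
         call. = FALSE)

  p <- best$par
  Do_hat <- if (fit_D_oil) exp(p[["lDo"]]) else D_oil
  se <- c(D33 = NA_real_, alpha = NA_real_)
  dof <- length(g) - length(p)
  if (dof > 0) {
    vc <- tryCatch(best$deviance / dof * solve(best$hessian),
                   error = function(e) NULL)
    if (!is.null(vc)) {
      se["D33"] <- sqrt(max(vc["D33", "D33"], 0))
      se["alpha"] <- sqrt(max(vc["alpha", "alpha"], 0))
    }
  }
  flags <- character(0)
  if (p[["D33"]] >= 0.99 * 100)
    flags <- c(flags, "unrestricted")
  droplet_size_distribution(p[["D33"]], p[["alpha"]], Do_hat, se,
                            sqrt(best$deviance), flags)
}

#' Droplet growth ratio
#'
#' D3,3(after) / D3,3(before): the factor by which the volume-weighted
#' median droplet diameter grew, e.g. through shear-induced coalescence.
#'
#' @param after,before `droplet_size_distribution` objects, or bare
#'   diameters in micrometres.
#' @return The dimensionless growth ratio.
#' @examples
#' growth_ratio(4.30, 3.39)  # 1.27
#' @export
growth_ratio <- function(after, before) {
  d_after <- if (inherits(after, "droplet_size_distribution"))
    after$D33 else as.numeric(after)
  d_before <- if (inherits(before, "droplet_size_distribution"))
    before$D33 else as.numeric(before)
  if (d_before <= 0) stop("baseline D3,3 must be positive", call. = FALSE)
  d_after / d_before
}
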