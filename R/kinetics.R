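#' Second-order structural-kinetic model parameters
#'
#' Parameters of the structural kinetic model (SKM) for yield-stress
#' breakdown under steady shear:
#' tau0(t) = (tau00 - tau0e) / (ks t + 1) + tau0e,
#' where `tau00` is the initial (structured) yield stress, `tau0e` the
#' equilibrium yield stress after prolonged shear, and `ks` the breakdown
#' rate in the inverse of whatever unit the time axis carries.
#'
#' @param tau00 Initial yield stress in Pa; must satisfy
#'   `tau00 >= tau0e >= 0`.
#' @param tau0e Equilibrium yield stress in Pa.
#' @param ks Breakdown rate (>= 0), inverse time units.
#' @return An object of class `skm_params`.
#' @examples
#' skm_params(80.1, 44, 0.012)
#' @export
skm_params <- function(tau00, tau0e, ks) {
  stopifnot(is.numeric(tau00), is.numeric(tau0e), is.numeric(ks))
  if (!(tau00 >= tau0e && tau0e >= 0))
    stop("need tau00 >= tau0e >= 0", call. = FALSE)
  if (ks < 0) stop("ks must be >= 0", call. = FALSE)
  structure(list(tau00 = tau00, tau0e = tau0e, ks = ks),
            class = "skm_params")
}

#' @export
print.skm_params <- function(x, ...) {
  cat(sprintf("SKM: tau0,0 = %.4g Pa, tau0,e = %.4g Pa, ks = %.4g (1/time unit)\n",
              x$tau00, x$tau0e, x$ks))
  invisible(x)
}

#' Evaluate the structural-kinetic yield-stress decay
#'
#' @param params An [skm_params()] object.
#' @param times Shearing times (>= 0), in the unit matching `ks`.
#' @return Yield stresses tau0(t) in Pa; equals `tau00` at t = 0 and tends
#'   to `tau0e` as t grows.
#' @export
skm_model <- function(params, times) {
  stopifnot(inherits(params, "skm_params"), all(times >= 0))
  (params$tau00 - params$tau0e) / (params$ks * times + 1) + params$tau0e
}

#' Synthetic yield-stress decay series
#'
#' @param params An [skm_params()].
#' @param times Sampling times (>= 0).
#' @param noise Optional [noise_spec()]; multiplicative sigma is a
#'   fraction of the local yield stress.
#' @return A data frame with columns `time` and `tau0` (Pa).
#' @export
skm_series <- function(params, times, noise = NULL) {
  tau0 <- apply_noise(skm_model(params, times), noise)
  data.frame(time = as.numeric(times), tau0 = tau0)
}

#' Fit the structural-kinetic model to a yield-stress time series
#'
#' Bounded least squares of tau0(t) = (tau00 - tau0e)/(ks t + 1) + tau0e,
#' parameterized internally as (tau0e, dtau = tau00 - tau0e, ks), all
#' constrained non-negative so tau00 >= tau0e >= 0 holds by construction.
#' Start values: tau00 from the earliest observation, tau0e from the
#' latest, ks = 1/median(times).  Uncertainties are 1-sigma values from the
#' Jacobian-based covariance at the optimum (delta method for tau00).
#'
#' The fit is unit-agnostic: `ks` is returned in the inverse of the unit of
#' `times`, recorded in the `time_unit` field — no silent conversion.
#'
#' A flat series returns `ks = 0` with flag `"flat"`; a series whose
#' duration satisfies `max(times) * ks < 0.1` is flagged
#' `"equilibrium_unreached"` because the plateau is then barely constrained
#' by the data.
#'
#' @param times Shearing times (>= 0, at least one positive), any unit.
#' @param tau0_values Observed yield stresses in Pa.
#' @param weights Optional non-negative weights (e.g. inverse variances
#'   from the flow-curve fits).
#' @param time_unit Label recorded with the fit (e.g. `"min"`).
#' @return An object of class `skm_fit`: `params` ([skm_params()]),
#'   `se` (named uncertainties), `breakdown_ratio`, `residual_norm`,
#'   `time_unit` and `flags`.
#' @examples
#' tt <- seq(0, 500, length.out = 20)
#' fit_skm(tt, skm_model(skm_params(80.1, 44, 0.012), tt), time_unit = "min")
#' @export
fit_skm <- function(times, tau0_values, weights = NULL, time_unit = "time") {
  stopifnot(is.numeric(times), is.numeric(tau0_values),
            length(times) == length(tau0_values))
  if (length(times) < 4L)
    stop("at least 4 points are needed for an SKM fit", call. = FALSE)
  if (any(times < 0) || !any(times > 0))
    stop("times must be >= 0 with at least one positive", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(times))
  stopifnot(all(weights >= 0))
  sw <- sqrt(weights)

  flags <- character(0)
  if (stats::sd(tau0_values) <= 1e-12 * max(abs(tau0_values), 1)) {
    m <- mean(tau0_values)
    params <- skm_params(m, m, 0)
    warning("flat yield-stress series: ks is unidentifiable, returning ks = 0",
            call. = FALSE)
    return(structure(
      list(params = params,
           se = c(tau00 = NA_real_, tau0e = NA_real_, ks = NA_real_),
           breakdown_ratio = 1, residual_norm = 0,
           time_unit = time_unit, flags = "flat"),
      class = "skm_fit"))
  }

  ord <- order(times)
  start <- c(tau0e = max(tau0_values[ord][length(times)], 1e-8),
             dtau = max(tau0_values[ord][1] - tau0_values[ord][length(times)],
                        1e-8),
             ks = 1 / stats::median(times[times > 0]))
  res_fn <- function(p) {
    sw * ((p[["dtau"]] / (p[["ks"]] * times + 1) + p[["tau0e"]]) - tau0_values)
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = res_fn, lower = c(0, 0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 100000, ftol = 1e-14,
                                         ptol = 1e-14))
  p <- fit$par
  params <- skm_params(p[["tau0e"]] + p[["dtau"]], p[["tau0e"]], p[["ks"]])

  se <- c(tau00 = NA_real_, tau0e = NA_real_, ks = NA_real_)
  dof <- length(times) - 3L
  if (dof > 0) {
    vc <- tryCatch(fit$deviance / dof * solve(fit$hessian),
                   error = function(e) NULL)
    if (!is.null(vc)) {
      se["tau0e"] <- sqrt(max(vc["tau0e", "tau0e"], 0))
      se["ks"] <- sqrt(max(vc["ks", "ks"], 0))
      se["tau00"] <- sqrt(max(vc["tau0e", "tau0e"] + vc["dtau", "dtau"] +
                                2 * vc["tau0e", "dtau"], 0))
    }
  }
  if (max(times) * params$ks < 0.1) {
    flags <- c(flags, "equilibrium_unreached")
    warning("max(times) * ks < 0.1: the series has not approached equilibrium; tau0e is poorly constrained",
            call. = FALSE)
  }
  structure(
    list(params = params, se = se,
         breakdown_ratio = if (params$tau0e > 0)
           params$tau00 / params$tau0e else NA_real_,
         residual_norm = sqrt(fit$deviance),
         time_unit = time_unit, flags = flags),
    class = "skm_fit")
}

#' @export
print.skm_fit <- function(x, ...) {
  cat(sprintf(
    "SKM fit: tau0,0 = %.4g +/- %.2g Pa, tau0,e = %.4g +/- %.2g Pa, ks = %.4g +/- %.2g 1/%s\n",
    x$params$tau00, x$se["tau00"], x$params$tau0e, x$se["tau0e"],
    x$params$ks, x$se["ks"], x$time_unit))
  cat(sprintf("  breakdown extent tau0,0/tau0,e = %.3g%s\n",
              x$breakdown_ratio,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Extent of structural breakdown
#'
#' The ratio tau0,0 / tau0,e between the initial and equilibrium yield
#' stress: 1 means no breakdown, larger values a larger loss of structure.
#'
#' @param fit An [skm_fit], [skm_params()] object, or any list carrying
#'   `tau00` and `tau0e` fields.
#' @return The dimensionless ratio; errors if `tau0e` is zero.
#' @examples
#' breakdown_ratio(skm_params(80.1, 44, 0.012))  # 1.82
#' @export
breakdown_ratio <- function(fit) {
  p <- if (inherits(fit, "skm_fit")) fit$params else fit
  if (is.null(p$tau00) || is.null(p$tau0e))
    stop("fit must carry tau00 and tau0e", call. = FALSE)
  if (p$tau0e <= 0)
    stop("tau0e must be positive to form the breakdown ratio", call. = FALSE)
  p$tau00 / p$tau0e
}
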