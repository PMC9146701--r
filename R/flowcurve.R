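#' Herschel-Bulkley fit of a local flow curve
#'
#' Bounded nonlinear least squares of sigma = tau0 + K gamma_dot^n with
#' tau0 >= 0, K > 0 and 0 < n <= 2.  Start values follow a deterministic
#' recipe (tau0 from the smallest stress, K from the log-log slope of the
#' excess stress, n = 0.5) and the fit is repeated from three jittered
#' starts; the solution with the smallest residual wins, ties broken by the
#' smaller tau0.  Uncertainties are 1-sigma values from the Jacobian-based
#' covariance at the optimum.
#'
#' @param lfc A [local_flow_curve()] with at least 4 distinct shear rates
#'   (3 when `n_fixed` is given).
#' @param n_fixed Optional fixed flow index; when supplied only tau0 and K
#'   are fitted.
#' @param robust Use a soft-L1 loss instead of plain least squares.
#' @return An object of class `hb_fit`: `params` ([hb_params()]), `se`,
#'   `residual_norm` (Pa), `time_stamp`, `n_fixed` flag.
#' @examples
#' gd <- c(0.5, 1, 2, 5, 10, 20)
#' lfc <- local_flow_curve(gd, hb_stress(hb_params(100, 30, 0.47), gd))
#' fit_hb(lfc)
#' @export
fit_hb <- function(lfc, n_fixed = NULL, robust = FALSE) {
  stopifnot(inherits(lfc, "local_flow_curve"))
  gd <- lfc$gamma_dot; sg <- lfc$sigma
  need <- if (is.null(n_fixed)) 4L else 3L
  if (length(unique(gd)) < need)
    stop(sprintf("need at least %d distinct shear rates", need),
         call. = FALSE)
  if (max(gd) == min(gd))
    stop("degenerate flow curve: all shear rates equal", call. = FALSE)

  start <- .hb_start(gd, sg, n_fixed)
  jitters <- list(c(1, 1, 1), c(0.5, 2, 0.8 / start[["n"]] * 1),
                  c(1.5, 0.5, 1.4 / start[["n"]] * 1))
  # jitters multiply (tau0, K, n) start; n jitter expressed as target values
  starts <- lapply(jitters, function(j) {
    s <- start
    s[["tau0"]] <- s[["tau0"]] * j[1]
    s[["K"]] <- s[["K"]] * j[2]
    if (is.null(n_fixed)) s[["n"]] <- min(max(s[["n"]] * j[3], 0.05), 2)
    s
  })

  best <- NULL
  for (s in starts) {
    f <- .hb_solve(gd, sg, s, n_fixed, robust)
    if (is.null(f)) next
    if (is.null(best) || f$deviance < best$deviance - 1e-12 ||
        (abs(f$deviance - best$deviance) <= 1e-12 &&
         f$par[["tau0"]] < best$par[["tau0"]]))
      best <- f
  }
  if (is.null(best))
    stop("Herschel-Bulkley fit failed to converge from all start points; ",
         "starts tried: ",
         paste(vapply(starts, function(s)
           sprintf("(tau0=%.3g, K=%.3g, n=%.3g)", s[["tau0"]], s[["K"]],
                   if (is.null(n_fixed)) s[["n"]] else n_fixed), ""),
           collapse = ", "),
         call. = FALSE)

  p <- best$par
  n_val <- if (is.null(n_fixed)) p[["n"]] else n_fixed
  params <- hb_params(p[["tau0"]], p[["K"]], n_val)
  se <- c(tau0 = NA_real_, K = NA_real_, n = NA_real_)
  dof <- length(gd) - length(p)
  if (dof > 0) {
    vc <- tryCatch(best$deviance / dof * solve(best$hessian),
                   error = function(e) NULL)
    if (!is.null(vc)) {
      se["tau0"] <- sqrt(max(vc["tau0", "tau0"], 0))
      se["K"] <- sqrt(max(vc["K", "K"], 0))
      if (is.null(n_fixed)) se["n"] <- sqrt(max(vc["n", "n"], 0))
    }
  }
  structure(
    list(params = params, se = se, residual_norm = sqrt(best$deviance),
         time_stamp = lfc$time_stamp, n_fixed = !is.null(n_fixed)),
    class = "hb_fit")
}

.hb_start <- function(gd, sg, n_fixed) {
  tau0_0 <- max(0, min(sg)) * 0.95
  excess <- pmax(sg - tau0_0, 1e-6 * max(sg))
  pos <- gd > 0
  n0 <- if (is.null(n_fixed)) 0.5 else n_fixed
  K0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(excess[pos]) ~ log(gd[pos])))
    exp(sl[[1]])
  } else max(sg) / max(gd)^n0
  c(tau0 = tau0_0, K = max(K0, 1e-8), n = n0)
}

.hb_solve <- function(gd, sg, start, n_fixed, robust) {
  soft_l1 <- function(r) {
    s <- stats::mad(r, constant = 1.4826) + 1e-12
    sign(r) * sqrt(2 * (sqrt(1 + (r / s)^2) - 1)) * s
  }
  if (is.null(n_fixed)) {
    par <- start
    fn <- function(p) {
      r <- p[["tau0"]] + p[["K"]] * gd^p[["n"]] - sg
      if (robust) soft_l1(r) else r
    }
    lower <- c(0, 1e-12, 1e-3); upper <- c(Inf, Inf, 2)
  } else {
    par <- start[c("tau0", "K")]
    fn <- function(p) {
      r <- p[["tau0"]] + p[["K"]] * gd^n_fixed - sg
      if (robust) soft_l1(r) else r
    }
    lower <- c(0, 1e-12); upper <- c(Inf, Inf)
  }
  tryCatch({
    f <- minpack.lm::nls.lm(
      par = par, fn = fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 200000,
                                           ftol = 1e-13, ptol = 1e-13))
    if (f$info %in% c(-1, 0, 5, 9)) NULL else f
  }, error = function(e) NULL)
}

#' @export
print.hb_fit <- function(x, ...) {
  cat(sprintf(
    "HB fit: tau0 = %.4g +/- %.2g Pa, K = %.4g +/- %.2g Pa.s^n, n = %.4g%s\n",
    x$params$tau0, x$se["tau0"], x$params$K, x$se["K"], x$params$n,
    if (x$n_fixed) " (fixed)" else sprintf(" +/- %.2g", x$se["n"])))
  invisible(x)
}

#' Joint Herschel-Bulkley fit with one global flow index
#'
#' Fits a time-ordered list of local flow curves jointly: each curve gets
#' its own yield stress tau0 and consistency K, while a single flow index n
#' is shared across all curves.  The per-curve tau0 values form the
#' yield-stress decay series passed on to the kinetics stage.  Start values
#' come from independent per-curve fits (shared n started at their median).
#'
#' @param lfcs List of [local_flow_curve()] objects (>= 1; a single curve
#'   degenerates to [fit_hb()]).
#' @param robust Use a soft-L1 loss.
#' @param weights Per-curve weights: `NULL` (equal, the default),
#'   `"auto"` (inverse residual variance of the independent per-curve
#'   fits — useful when curves from different rotor rates carry different
#'   noise levels), or a numeric vector of length `length(lfcs)`.
#' @return For one curve, an `hb_fit`.  Otherwise an object of class
#'   `hb_global_fit`: `fits` (list of per-curve `hb_fit`, all sharing `n`),
#'   `n`, `n_se`, `residual_norm`, and `yield_stress_series` (data frame
#'   of `time`, `tau0`, `tau0_se`).
#' @export
fit_hb_global_n <- function(lfcs, robust = FALSE, weights = NULL) {
  if (inherits(lfcs, "local_flow_curve")) lfcs <- list(lfcs)
  stopifnot(length(lfcs) >= 1L,
            all(vapply(lfcs, inherits, TRUE, "local_flow_curve")))
  if (length(lfcs) == 1L) return(fit_hb(lfcs[[1]], robust = robust))

  singles <- lapply(lfcs, fit_hb, robust = robust)
  n0 <- stats::median(vapply(singles, function(f) f$params$n, 0))
  m <- length(lfcs)
  w <- if (is.null(weights)) rep(1, m)
  else if (identical(weights, "auto")) {
    v <- vapply(seq_len(m), function(i)
      singles[[i]]$residual_norm^2 /
        max(1L, length(lfcs[[i]]$gamma_dot) - 3L), 0)
    v <- pmax(v, 1e-12 * max(v))
    min(v) / v
  } else {
    stopifnot(is.numeric(weights), length(weights) == m, all(weights > 0))
    weights / max(weights)
  }
  sw <- sqrt(w)
  fn <- function(p) {
    unlist(lapply(seq_len(m), function(i) {
      sw[i] * (p[[paste0("tau0_", i)]] +
                 p[[paste0("K_", i)]] * lfcs[[i]]$gamma_dot^p[["n"]] -
                 lfcs[[i]]$sigma)
    }), use.names = FALSE)
  }
  lower <- c(1e-3, rep(0, m), rep(1e-12, m))
  upper <- c(2, rep(Inf, 2 * m))
  # the shared-n likelihood can be flat on narrow shear-rate ranges:
  # start from several n values and keep the best solution
  fit <- NULL
  for (n_start in unique(c(n0, 0.3, 0.6, 1))) {
    par <- c(n = min(max(n_start, 0.05), 2),
             stats::setNames(vapply(singles, function(f) f$params$tau0, 0),
                             paste0("tau0_", seq_len(m))),
             stats::setNames(vapply(singles, function(f) f$params$K, 0),
                             paste0("K_", seq_len(m))))
    f <- tryCatch(minpack.lm::nls.lm(
      par = par, fn = fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 500000,
                                           ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(f) || f$info %in% c(-1, 0, 5, 9)) next
    if (is.null(fit) || f$deviance < fit$deviance) fit <- f
  }
  if (is.null(fit))
    stop("global-n fit did not converge from any start (n tried: ",
         paste(signif(unique(c(n0, 0.3, 0.6, 1)), 3), collapse = ", "),
         ")", call. = FALSE)

  p <- fit$par
  npts <- sum(vapply(lfcs, function(l) length(l$gamma_dot), 0L))
  dof <- npts - length(p)
  vc <- if (dof > 0)
    tryCatch(fit$deviance / dof * solve(fit$hessian),
             error = function(e) NULL) else NULL
  se_of <- function(nm) if (is.null(vc)) NA_real_ else
    sqrt(max(vc[nm, nm], 0))

  fits <- lapply(seq_len(m), function(i) {
    structure(
      list(params = hb_params(p[[paste0("tau0_", i)]],
                              p[[paste0("K_", i)]], p[["n"]]),
           se = c(tau0 = se_of(paste0("tau0_", i)),
                  K = se_of(paste0("K_", i)), n = se_of("n")),
           residual_norm = NA_real_,
           time_stamp = lfcs[[i]]$time_stamp, n_fixed = FALSE),
      class = "hb_fit")
  })
  series <- data.frame(
    time = vapply(lfcs, function(l) l$time_stamp, 0),
    tau0 = vapply(fits, function(f) f$params$tau0, 0),
    tau0_se = vapply(fits, function(f) unname(f$se["tau0"]), 0))
  structure(
    list(fits = fits, n = p[["n"]], n_se = se_of("n"),
         residual_norm = sqrt(fit$deviance),
         yield_stress_series = series),
    class = "hb_global_fit")
}

#' @export
print.hb_global_fit <- function(x, ...) {
  cat(sprintf("Global-n HB fit over %d flow curves: n = %.4g +/- %.2g\n",
              length(x$fits), x$n, x$n_se))
  cat(sprintf("  tau0 series: %s Pa\n",
              paste(sprintf("%.4g", x$yield_stress_series$tau0),
                    collapse = ", ")))
  invisible(x)
}

#' Bulk emulsion properties for dimensionless scaling
#'
#' @param interfacial_tension Oil/water interfacial tension in N/m.
#' @param continuous_phase_viscosity Continuous-phase viscosity in Pa s.
#' @param droplet_radius Average droplet radius in metres.
#' @param volume_fraction Dispersed-phase volume fraction in (0, 1).
#' @return An object of class `emulsion_properties`.
#' @export
emulsion_properties <- function(interfacial_tension,
                                continuous_phase_viscosity,
                                droplet_radius, volume_fraction) {
  stopifnot(interfacial_tension > 0, continuous_phase_viscosity > 0,
            droplet_radius > 0, volume_fraction > 0, volume_fraction < 1)
  structure(list(interfacial_tension = interfacial_tension,
                 continuous_phase_viscosity = continuous_phase_viscosity,
                 droplet_radius = droplet_radius,
                 volume_fraction = volume_fraction),
            class = "emulsion_properties")
}

#' Dimensionless viscous stress versus capillary number
#'
#' Scales the viscous part of a fitted Herschel-Bulkley law,
#' tau_v = K gamma_dot^n, by droplet radius R and interfacial tension
#' sigma_i to the dimensionless form tau_v R / sigma_i, and pairs it with
#' the capillary number Ca = mu gamma_dot R / sigma_i.  Curves measured at
#' different stages of shear but sharing (K, n) collapse in this
#' representation regardless of their yield stress.
#'
#' @param hbfit An [hb_fit] (or an [hb_params()] object).
#' @param props An [emulsion_properties()].
#' @param gamma_dot Shear rates in 1/s.
#' @return A data frame with columns `Ca` and `scaled_viscous_stress`.
#' @export
dimensionless_viscous_stress <- function(hbfit, props, gamma_dot) {
  stopifnot(inherits(props, "emulsion_properties"), all(gamma_dot >= 0))
  hb <- if (inherits(hbfit, "hb_fit")) hbfit$params else hbfit
  stopifnot(inherits(hb, "hb_params"))
  if (props$interfacial_tension <= 0)
    stop("interfacial tension must be positive", call. = FALSE)
  tau_v <- hb$K * gamma_dot^hb$n
  data.frame(
    Ca = props$continuous_phase_viscosity * gamma_dot *
      props$droplet_radius / props$interfacial_tension,
    scaled_viscous_stress = tau_v * props$droplet_radius /
      props$interfacial_tension)
}
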