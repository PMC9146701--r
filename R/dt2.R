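#' Log-spaced grid
#'
#' @param from,to Range (positive).
#' @param n Number of points.
#' @return Geometrically spaced values from `from` to `to`.
#' @export
log_grid <- function(from, to, n) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

#' D-T2 dataset: a PGSE-CPMG decay surface
#'
#' Signal matrix S(g, t) from a diffusion-encoded CPMG experiment: one row
#' per gradient strength, one column per echo.  Echo times must be the
#' regular CPMG comb `tE * (1..N)`.
#'
#' @param gradient_strengths Gradient amplitudes in T/m.
#' @param echo_times Echo times in seconds.
#' @param signal Matrix, `length(gradient_strengths)` x
#'   `length(echo_times)`.
#' @param pgse A [pgse_params()] describing the diffusion encoding.
#' @param echo_spacing CPMG echo spacing tE in seconds.
#' @return An object of class `dt2_dataset`.
#' @export
dt2_dataset <- function(gradient_strengths, echo_times, signal, pgse,
                        echo_spacing) {
  stopifnot(is.matrix(signal), inherits(pgse, "pgse_params"))
  if (nrow(signal) != length(gradient_strengths) ||
      ncol(signal) != length(echo_times))
    stop("signal matrix dimensions must match the gradient and echo axes",
         call. = FALSE)
  if (max(abs(echo_times - echo_spacing * seq_along(echo_times))) >
      1e-9 * echo_spacing)
    stop("echo times must be the regular comb tE * (1..N)", call. = FALSE)
  structure(list(gradient_strengths = as.numeric(gradient_strengths),
                 echo_times = as.numeric(echo_times),
                 signal = signal, pgse = pgse,
                 echo_spacing = echo_spacing),
            class = "dt2_dataset")
}

#' @export
print.dt2_dataset <- function(x, ...) {
  cat(sprintf("D-T2 dataset: %d gradients x %d echoes (tE = %.3g ms)\n",
              nrow(x$signal), ncol(x$signal), x$echo_spacing * 1e3))
  invisible(x)
}

#' Synthesize a multi-exponential D-T2 decay surface
#'
#' Forward model with exponential behaviour in both encoding dimensions
#' (the assumption the 2D inverse Laplace inversion relies on):
#' S(g, t) = sum_k A_k exp(-b(g) D_k) exp(-t / T2_k), with
#' b(g) = gamma^2 g^2 delta^2 (Delta - delta/3).
#'
#' @param components Data frame with columns `amplitude`, `D` (m^2/s) and
#'   `T2` (s), one row per component; all positive.
#' @param pgse A [pgse_params()]; its gradient table forms the g axis.
#' @param echo_times Echo times in seconds, a regular comb.
#' @param noise Optional [noise_spec()] (additive sigma in signal units).
#' @return A [dt2_dataset()].
#' @examples
#' comp <- data.frame(amplitude = c(0.22, 0.78), D = c(9e-10, 4e-12),
#'                    T2 = c(0.4, 0.12))
#' p <- pgse_params(seq(0.1, 6.6, length.out = 32), 1e-3, 200e-3)
#' dt2_signal(comp, p, 2.2e-3 * (1:64))
#' @export
dt2_signal <- function(components, pgse, echo_times, noise = NULL) {
  stopifnot(is.data.frame(components),
            all(c("amplitude", "D", "T2") %in% names(components)),
            all(components$amplitude > 0), all(components$D > 0),
            all(components$T2 > 0), inherits(pgse, "pgse_params"))
  b <- stejskal_tanner_b(pgse)
  S <- matrix(0, length(b), length(echo_times))
  for (k in seq_len(nrow(components)))
    S <- S + components$amplitude[k] *
      outer(exp(-b * components$D[k]),
            exp(-echo_times / components$T2[k]))
  tE <- echo_times[1]
  dt2_dataset(pgse$gradient_strengths, echo_times, apply_noise(S, noise),
              pgse, tE)
}

#' Exponential kernel matrices for the 2D inversion
#'
#' K1\[i, k\] = exp(-b(g_i) D_k) for the diffusion dimension and
#' K2\[j, l\] = exp(-t_j / T2_l) for the relaxation dimension, so that the
#' forward model is S = K1 F K2'.
#'
#' @param dataset A [dt2_dataset()].
#' @param D_grid,T2_grid Log-spaced grids for diffusivity (m^2/s) and T2
#'   (s), at least 8 points each.
#' @return List with matrices `K1`, `K2` and the weighting vector `b`.
#' @export
build_kernels <- function(dataset, D_grid, T2_grid) {
  stopifnot(inherits(dataset, "dt2_dataset"), length(D_grid) >= 8,
            length(T2_grid) >= 8, all(D_grid > 0), all(T2_grid > 0))
  b <- stejskal_tanner_b(dataset$pgse, dataset$gradient_strengths)
  if (max(b) * max(D_grid) < 3 || max(dataset$echo_times) / min(T2_grid) < 3)
    warning("grid may not cover the decay range of the data", call. = FALSE)
  list(K1 = exp(-outer(b, D_grid)),
       K2 = exp(-outer(dataset$echo_times, 1 / T2_grid)),
       b = b)
}

# Non-negative Tikhonov solve of min |K1 F K2' - S|^2 + lambda |F|^2
# by L-BFGS-B on vec(F) with analytic gradient.
.nn_tikhonov <- function(K1, K2, S, lambda, F0 = NULL,
                         factr = 10, maxit = 3000) {
  nd <- ncol(K1); nt <- ncol(K2)
  G1 <- crossprod(K1); G2 <- crossprod(K2)
  B <- crossprod(K1, S) %*% K2  # K1' S K2
  obj <- function(f) {
    FF <- matrix(f, nd, nt)
    M <- K1 %*% FF %*% t(K2) - S
    sum(M * M) + lambda * sum(FF * FF)
  }
  grad <- function(f) {
    FF <- matrix(f, nd, nt)
    as.vector(2 * (G1 %*% FF %*% G2 - B + lambda * FF))
  }
  f0 <- if (is.null(F0)) rep(0, nd * nt) else as.vector(F0)
  opt <- stats::optim(f0, obj, grad, method = "L-BFGS-B",
                      lower = 0,
                      control = list(maxit = maxit, factr = factr))
  matrix(opt$par, nd, nt)
}

#' D-T2 correlation map
#'
#' Non-negative amplitude density on a log-spaced (D, T2) grid, with the
#' regularization weight used, detected peaks, and solver diagnostics.
#'
#' @keywords internal
dt2_map <- function(D_grid, T2_grid, amplitude, reg_weight, residual_norm,
                    noise_estimate, peaks = NULL) {
  structure(list(D_grid = D_grid, T2_grid = T2_grid, amplitude = amplitude,
                 reg_weight = reg_weight, residual_norm = residual_norm,
                 noise_estimate = noise_estimate, peaks = peaks),
            class = "dt2_map")
}

#' @export
print.dt2_map <- function(x, ...) {
  cat(sprintf(
    "D-T2 map: %d x %d grid, lambda = %.3g, total mass %.4g, %d peak(s)\n",
    length(x$D_grid), length(x$T2_grid), x$reg_weight, sum(x$amplitude),
    if (is.null(x$peaks)) 0L else nrow(x$peaks)))
  invisible(x)
}

#' 2D inverse Laplace inversion of a D-T2 decay surface
#'
#' Solves min ||K1 F K2' - S||^2 + lambda ||F||^2 subject to F >= 0, after
#' SVD compression of both exponential kernels (singular values below
#' `sv_tol` times the largest are dropped, which reduces the data to its
#' numerically informative subspace).  The bound-constrained quadratic
#' program is solved by L-BFGS-B with an analytic gradient.
#'
#' The regularization weight can be given explicitly (for exact
#' reproducibility) or chosen automatically by the discrepancy principle:
#' the noise level is estimated from the tail of the highest-gradient echo
#' train, and the largest lambda whose full-space residual stays within
#' `discrepancy_factor` times the expected noise norm is selected from a
#' geometric sweep.
#'
#' @param dataset A [dt2_dataset()].
#' @param D_grid,T2_grid Log-spaced inversion grids; defaults 64 points
#'   over 1e-13 to 1e-8 m^2/s and 1 ms to 3 s.
#' @param reg_weight `"auto"` or a non-negative number.
#' @param sv_tol Relative singular-value cutoff for kernel compression.
#' @param discrepancy_factor Multiplier on the expected noise norm.
#' @param n_lambda,lambda_range Geometric sweep settings for `"auto"`
#'   (range is relative to the squared product of the kernels' largest
#'   singular values).
#' @param peak_mass_threshold Minimum fraction of total mass for a region
#'   to be reported as a peak.
#' @return A `dt2_map` with fields `D_grid`, `T2_grid`, `amplitude`
#'   (non-negative matrix, rows D), `reg_weight`, `residual_norm`,
#'   `noise_estimate` and `peaks` (data frame: `D`, `T2`, `mass`,
#'   `D_centroid`, `T2_centroid`).
#' @export
ilt2d <- function(dataset, D_grid = log_grid(1e-13, 1e-8, 64),
                  T2_grid = log_grid(1e-3, 3, 64),
                  reg_weight = "auto", sv_tol = 1e-8,
                  discrepancy_factor = 1.1, n_lambda = 16L,
                  lambda_range = c(1e-10, 1),
                  peak_mass_threshold = 0.01) {
  stopifnot(inherits(dataset, "dt2_dataset"))
  S <- dataset$signal
  if (all(S == 0)) {
    return(dt2_map(D_grid, T2_grid,
                   matrix(0, length(D_grid), length(T2_grid)),
                   reg_weight = if (identical(reg_weight, "auto")) 0
                   else reg_weight,
                   residual_norm = 0, noise_estimate = 0,
                   peaks = .empty_peaks()))
  }
  ker <- build_kernels(dataset, D_grid, T2_grid)

  sv1 <- svd(ker$K1); sv2 <- svd(ker$K2)
  r1 <- sum(sv1$d > sv_tol * sv1$d[1]); r2 <- sum(sv2$d > sv_tol * sv2$d[1])
  if (r1 < 2L || r2 < 2L)
    stop(sprintf(
      "kernel compression collapsed (ranks %d x %d at sv_tol = %g)",
      r1, r2, sv_tol), call. = FALSE)
  K1c <- diag(sv1$d[1:r1], r1) %*% t(sv1$v[, 1:r1, drop = FALSE])
  K2c <- diag(sv2$d[1:r2], r2) %*% t(sv2$v[, 1:r2, drop = FALSE])
  Sc <- t(sv1$u[, 1:r1, drop = FALSE]) %*% S %*% sv2$u[, 1:r2, drop = FALSE]

  # noise estimate: tail of the echo train at the strongest gradient
  tail_n <- max(8L, ncol(S) %/% 8L)
  tail_vals <- S[which.max(dataset$gradient_strengths),
                 (ncol(S) - tail_n + 1L):ncol(S)]
  noise_sd <- max(stats::sd(tail_vals), 1e-12 * max(abs(S)))

  full_resid <- function(FF)
    sqrt(sum((ker$K1 %*% FF %*% t(ker$K2) - S)^2))

  scale2 <- (sv1$d[1] * sv2$d[1])^2
  if (identical(reg_weight, "auto")) {
    lams <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                    length.out = n_lambda)) * scale2
    target <- discrepancy_factor * noise_sd * sqrt(length(S))
    FF <- NULL; chosen <- lams[1]; chosen_F <- NULL
    for (lam in lams) {
      FF <- .nn_tikhonov(K1c, K2c, Sc, lam, F0 = FF)
      if (full_resid(FF) <= target) {
        chosen <- lam; chosen_F <- FF
      } else if (!is.null(chosen_F)) break
    }
    if (is.null(chosen_F)) {  # even the smallest lambda misses: keep it
      chosen <- lams[1]
      chosen_F <- .nn_tikhonov(K1c, K2c, Sc, chosen)
    }
    lambda <- chosen; FF <- chosen_F
  } else {
    stopifnot(is.numeric(reg_weight), reg_weight >= 0)
    lambda <- reg_weight
    FF <- .nn_tikhonov(K1c, K2c, Sc, lambda)
  }
  map <- dt2_map(D_grid, T2_grid, FF, lambda, full_resid(FF), noise_sd)
  map$peaks <- find_map_peaks(map, mass_threshold = peak_mass_threshold)
  map
}

.empty_peaks <- function() {
  data.frame(D = numeric(0), T2 = numeric(0), mass = numeric(0),
             D_centroid = numeric(0), T2_centroid = numeric(0))
}

#' Detect peaks in a D-T2 map
#'
#' Cells above a small amplitude floor (1% of the maximum) are labelled
#' into 4-connected regions; regions carrying at least `mass_threshold` of
#' the total mass are reported with the coordinates of their maximum cell
#' and their mass-weighted centroids (computed in log coordinates).
#'
#' @param map A `dt2_map`.
#' @param mass_threshold Minimum region mass as a fraction of total.
#' @param amplitude_floor Labelling floor as a fraction of the maximum
#'   amplitude.
#' @return Data frame `D`, `T2`, `mass`, `D_centroid`, `T2_centroid`,
#'   ordered by decreasing mass.
#' @export
find_map_peaks <- function(map, mass_threshold = 0.01,
                           amplitude_floor = 0.01) {
  stopifnot(inherits(map, "dt2_map"))
  FF <- map$amplitude
  total <- sum(FF)
  if (total <= 0) return(.empty_peaks())
  mask <- FF > amplitude_floor * max(FF)
  labels <- EBImage::bwlabel(mask)
  out <- .empty_peaks()
  for (lab in seq_len(max(labels))) {
    sel <- labels == lab
    mass <- sum(FF[sel])
    if (mass < mass_threshold * total) next
    idx <- which(sel & FF == max(FF[sel]), arr.ind = TRUE)[1, ]
    cells <- which(sel, arr.ind = TRUE)
    w <- FF[sel] / mass
    out <- rbind(out, data.frame(
      D = map$D_grid[idx[1]], T2 = map$T2_grid[idx[2]], mass = mass,
      D_centroid = exp(sum(w * log(map$D_grid[cells[, 1]]))),
      T2_centroid = exp(sum(w * log(map$T2_grid[cells[, 2]])))))
  }
  out[order(-out$mass), , drop = FALSE]
}

#' Extract the aqueous-phase (water) peak from a D-T2 map
#'
#' Among the detected peaks, the aqueous phase is the component with the
#' highest diffusion coordinate — free water diffuses orders of magnitude
#' faster than oil confined in droplets.  Ties in D are broken
#' deterministically by the larger mass.  The reported T2 is the
#' mass-weighted mean T2 of the peak's region.
#'
#' @param map A `dt2_map` (peaks are recomputed if absent).
#' @param ... Passed to [find_map_peaks()] when recomputing.
#' @return List with `D` (m^2/s), `T2` (s) and `mass`.
#' @export
extract_water_peak <- function(map, ...) {
  stopifnot(inherits(map, "dt2_map"))
  peaks <- if (is.null(map$peaks)) find_map_peaks(map, ...) else map$peaks
  if (nrow(peaks) == 0L)
    stop("no peak above threshold in the D-T2 map", call. = FALSE)
  ord <- order(-peaks$D, -peaks$mass)
  top <- peaks[ord[1], ]
  list(D = top$D, T2 = top$T2_centroid, mass = top$mass)
}

#' Linear calibration of water T2 against protein concentration
#'
#' Ordinary least squares of T2,w versus dissolved-protein concentration.
#' In protein-stabilized emulsions the water T2 decreases linearly with
#' the concentration of dissolved protein, making T2,w a proxy for protein
#' release into the continuous phase.
#'
#' @param concentrations Protein concentrations (any consistent unit),
#'   >= 3 values.
#' @param T2w_values Water-phase T2 values (s or ms, consistent).
#' @return An object of class `t2_calibration` with `slope`, `intercept`,
#'   `r_squared` and `n`.
#' @export
t2_concentration_fit <- function(concentrations, T2w_values) {
  stopifnot(is.numeric(concentrations), is.numeric(T2w_values),
            length(concentrations) == length(T2w_values))
  if (length(concentrations) < 3L)
    stop("at least 3 concentrations are required", call. = FALSE)
  fit <- stats::lm(T2w_values ~ concentrations)
  tss <- sum((T2w_values - mean(T2w_values))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(concentrations)),
            class = "t2_calibration")
}

#' @export
print.t2_calibration <- function(x, ...) {
  cat(sprintf("T2,w calibration: slope %.4g, intercept %.4g, r^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Root-mean-square diffusion length
#'
#' The 1D diffusion length sqrt(2 D Delta) travelled during the
#' observation time: the scale against which restriction by droplet walls
#' is judged.
#'
#' @param D Diffusivity in m^2/s (> 0).
#' @param Delta Observation time in s (>= 0).
#' @return Length in metres.
#' @examples
#' diffusion_length(9e-10, 0.2)  # ~19 um
#' @export
diffusion_length <- function(D, Delta) {
  stopifnot(all(D > 0), all(Delta >= 0))
  sqrt(2 * D * Delta)
}
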