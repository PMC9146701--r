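#' Pulsed-gradient spin-echo acquisition parameters
#'
#' Holds the gradient table and timing of a PGSE diffusion experiment:
#' gradient pulse width `delta`, diffusion (observation) time `Delta`,
#' and the gyromagnetic ratio of the observed nucleus (1H by default).
#'
#' @param gradient_strengths Gradient amplitudes in T/m, non-negative and
#'   strictly increasing.
#' @param delta Effective gradient pulse width in seconds (> 0).
#' @param Delta Effective diffusion time in seconds (> `delta`).
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#'
#' @return An object of class `pgse_params`.
#' @examples
#' pgse_params(seq(0.1, 6.6, length.out = 32), delta = 1e-3, Delta = 200e-3)
#' @export
pgse_params <- function(gradient_strengths, delta, Delta,
                        gamma = 2.6752218744e8) {
  stopifnot(is.numeric(gradient_strengths), is.numeric(delta),
            is.numeric(Delta), is.numeric(gamma))
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (Delta <= delta) stop("Delta must exceed delta", call. = FALSE)
  if (any(gradient_strengths < 0))
    stop("gradient strengths must be non-negative", call. = FALSE)
  if (length(gradient_strengths) > 1L &&
      any(diff(gradient_strengths) <= 0))
    stop("gradient strengths must be strictly increasing", call. = FALSE)
  structure(
    list(gradient_strengths = as.numeric(gradient_strengths),
         delta = delta, Delta = Delta, gamma = gamma),
    class = "pgse_params"
  )
}

#' @export
print.pgse_params <- function(x, ...) {
  cat(sprintf(
    "PGSE: %d gradient steps in [%.3g, %.3g] T/m, delta = %.3g ms, Delta = %.3g ms\n",
    length(x$gradient_strengths), min(x$gradient_strengths),
    max(x$gradient_strengths), x$delta * 1e3, x$Delta * 1e3))
  invisible(x)
}

#' Stejskal-Tanner diffusion weighting
#'
#' b(g) = gamma^2 g^2 delta^2 (Delta - delta/3), the weighting factor such
#' that a freely diffusing species with diffusivity D attenuates as
#' exp(-b D).
#'
#' @param pgse A [pgse_params()] object.
#' @param g Gradient strengths in T/m; defaults to the acquisition table.
#' @return Weighting factors in s m^-2.
#' @export
stejskal_tanner_b <- function(pgse, g = pgse$gradient_strengths) {
  stopifnot(inherits(pgse, "pgse_params"))
  pgse$gamma^2 * g^2 * pgse$delta^2 * (pgse$Delta - pgse$delta / 3)
}
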