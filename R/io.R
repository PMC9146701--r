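# CSV schemas with unit-bearing headers.  Numbers are written with 17
# significant digits so every schema round-trips at full double precision.

.write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

.numeric_cols <- function(df) {
  for (j in seq_along(df))
    if (is.integer(df[[j]])) df[[j]] <- as.numeric(df[[j]])
  df
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read and write velocity-profile CSVs
#'
#' Schema: columns `r_m` (radial position, metres, strictly ascending) and
#' `v_m_per_s` (azimuthal velocity); optional `time_min` and
#' `applied_per_s` columns carry the time stamp and nominal rate.  Extra
#' columns are accepted and preserved in the `extra` attribute.
#'
#' @param profile A [velocity_profile()].
#' @param path File path.
#' @return `write_profile_csv` returns `path` invisibly;
#'   `read_profile_csv` returns a `velocity_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "velocity_profile"))
  df <- data.frame(r_m = profile$r, v_m_per_s = profile$v)
  if (is.finite(profile$time_stamp)) df$time_min <- profile$time_stamp
  if (is.finite(profile$applied_rate))
    df$applied_per_s <- profile$applied_rate
  .write_csv_exact(df, path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- .numeric_cols(utils::read.csv(path, check.names = FALSE))
  .require_cols(df, c("r_m", "v_m_per_s"), path)
  if (any(diff(df$r_m) <= 0))
    stop(sprintf("%s: column r_m must be strictly ascending", path),
         call. = FALSE)
  prof <- velocity_profile(
    df$r_m, df$v_m_per_s,
    time_stamp = if ("time_min" %in% names(df)) df$time_min[1] else NA_real_,
    applied_rate = if ("applied_per_s" %in% names(df))
      df$applied_per_s[1] else NA_real_)
  extra <- setdiff(names(df),
                   c("r_m", "v_m_per_s", "time_min", "applied_per_s"))
  if (length(extra)) attr(prof, "extra") <- df[extra]
  prof
}

#' Read and write local-flow-curve CSVs
#'
#' Schema: `gamma_dot_per_s`, `sigma_Pa`, optional `r_m` and `time_min`.
#'
#' @param lfc A [local_flow_curve()].
#' @param path File path.
#' @export
write_lfc_csv <- function(lfc, path) {
  stopifnot(inherits(lfc, "local_flow_curve"))
  df <- data.frame(gamma_dot_per_s = lfc$gamma_dot, sigma_Pa = lfc$sigma)
  if (!is.null(lfc$r)) df$r_m <- lfc$r
  if (is.finite(lfc$time_stamp)) df$time_min <- lfc$time_stamp
  .write_csv_exact(df, path)
  invisible(path)
}

#' @rdname write_lfc_csv
#' @export
read_lfc_csv <- function(path) {
  df <- .numeric_cols(utils::read.csv(path, check.names = FALSE))
  .require_cols(df, c("gamma_dot_per_s", "sigma_Pa"), path)
  local_flow_curve(
    df$gamma_dot_per_s, df$sigma_Pa,
    r = if ("r_m" %in% names(df)) df$r_m else NULL,
    time_stamp = if ("time_min" %in% names(df)) df$time_min[1] else NA_real_)
}

#' Read and write yield-stress series CSVs
#'
#' Schema: `t_min` (shearing time) and `tau0_Pa`, with optional
#' `tau0_err_Pa`.
#'
#' @param series Data frame with columns `time`, `tau0` and optionally
#'   `tau0_se`.
#' @param path File path.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(is.data.frame(series), all(c("time", "tau0") %in% names(series)))
  df <- data.frame(t_min = series$time, tau0_Pa = series$tau0)
  if ("tau0_se" %in% names(series)) df$tau0_err_Pa <- series$tau0_se
  .write_csv_exact(df, path)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- .numeric_cols(utils::read.csv(path, check.names = FALSE))
  .require_cols(df, c("t_min", "tau0_Pa"), path)
  out <- data.frame(time = df$t_min, tau0 = df$tau0_Pa)
  if ("tau0_err_Pa" %in% names(df)) out$tau0_se <- df$tau0_err_Pa
  out
}

#' Read and write PFG decay CSVs
#'
#' Schema: `g_T_per_m` (ascending gradient strengths) and `E`
#' (attenuation).
#'
#' @param decay A [pfg_decay()].
#' @param path File path.
#' @export
write_decay_csv <- function(decay, path) {
  stopifnot(inherits(decay, "pfg_decay"))
  .write_csv_exact(data.frame(g_T_per_m = decay$gradient_strengths,
                              E = decay$attenuation), path)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  df <- .numeric_cols(utils::read.csv(path, check.names = FALSE))
  .require_cols(df, c("g_T_per_m", "E"), path)
  pfg_decay(df$g_T_per_m, df$E)
}

#' Read and write D-T2 dataset CSV bundles
#'
#' A dataset is stored as four sibling files sharing a stem:
#' `<stem>_signal.csv` (matrix, no header), `<stem>_gradients.csv`
#' (`g_T_per_m`), `<stem>_echoes.csv` (`t_s`), and `<stem>_pgse.json`
#' (delta, Delta, gamma, echo spacing).
#'
#' @param dataset A [dt2_dataset()].
#' @param stem Path stem (no extension).
#' @export
write_dt2_csv <- function(dataset, stem) {
  stopifnot(inherits(dataset, "dt2_dataset"))
  utils::write.table(
    matrix(sprintf("%.17g", dataset$signal), nrow = nrow(dataset$signal)),
    paste0(stem, "_signal.csv"), sep = ",", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  .write_csv_exact(data.frame(g_T_per_m = dataset$gradient_strengths),
                   paste0(stem, "_gradients.csv"))
  .write_csv_exact(data.frame(t_s = dataset$echo_times),
                   paste0(stem, "_echoes.csv"))
  jsonlite::write_json(
    list(delta = dataset$pgse$delta, Delta = dataset$pgse$Delta,
         gamma = dataset$pgse$gamma, echo_spacing = dataset$echo_spacing),
    paste0(stem, "_pgse.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_dt2_csv
#' @export
read_dt2_csv <- function(stem) {
  g <- .numeric_cols(utils::read.csv(paste0(stem, "_gradients.csv")))
  .require_cols(g, "g_T_per_m", paste0(stem, "_gradients.csv"))
  tt <- .numeric_cols(utils::read.csv(paste0(stem, "_echoes.csv")))
  .require_cols(tt, "t_s", paste0(stem, "_echoes.csv"))
  S <- as.matrix(utils::read.csv(paste0(stem, "_signal.csv"),
                                 header = FALSE,
                                 colClasses = "numeric"))
  dimnames(S) <- NULL
  meta <- jsonlite::read_json(paste0(stem, "_pgse.json"),
                              simplifyVector = TRUE)
  pgse <- pgse_params(g$g_T_per_m, meta$delta, meta$Delta, meta$gamma)
  dt2_dataset(g$g_T_per_m, tt$t_s, S, pgse, meta$echo_spacing)
}
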