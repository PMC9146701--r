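#' Pipeline configuration
#'
#' Assembles the complete, explicit configuration for a pipeline run: cell
#' geometry, constitutive and kinetic parameters of the simulated emulsion,
#' acquisition parameter blocks for each NMR experiment, noise magnitudes
#' and the seeds that make every stochastic stage reproducible.  All
#' defaults describe a concentrated egg-yolk-type emulsion sheared at
#' nominal rates of 5 and 25 1/s: initial yield stresses of 80.1 and 99 Pa
#' decaying to 44 and 27 Pa with breakdown rates 0.012 and 0.06 per
#' minute, flow index 0.47, droplet median diameter 3.39 um (width 0.20)
#' growing to 4.30 um (width 0.40), oil diffusivity 4e-12 m^2/s, and a
#' water/oil D-T2 pair at 9e-10 and 4e-12 m^2/s.  Measuring at two rotor
#' rates matters: a 1 mm gap at a single rate only spans a factor ~2 in
#' local shear rate, too narrow to identify the flow index from noisy
#' profiles, while the pooled global-n fit across both rates covers more
#' than a decade.  The minispec gradient-pulse width (2 ms) and the cell
#' height (40 mm) are assumed values, marked as such in the config.
#'
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @param applied_rates Nominal applied shear rates in 1/s.
#' @param skm Named list (one entry per applied rate) of structural-kinetic
#'   parameters `c(tau00, tau0e, ks)` driving the simulated decay.
#' @param times Shearing times (minutes) at which flow profiles are taken.
#' @param velocity_noise_frac Additive velocity noise as a fraction of the
#'   rotor surface speed; the default 0.2% describes a signal-averaged
#'   high-SNR acquisition.  Differentiation amplifies velocity noise by
#'   roughly 1/(window span), so at 48.8 um resolution even 1% velocity
#'   noise leaves the flow index barely identifiable from the narrow
#'   shear-rate span of a 1 mm gap.
#' @param stress_noise_frac Multiplicative noise on the law-generated flow
#'   curves of the rheology stage.
#' @param decay_noise Additive noise sigma on PFG attenuations.
#' @param dt2_snr Signal-to-noise ratio of the D-T2 surface (amplitude of
#'   S(0,0) over additive noise sigma).
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            applied_rates = c(5, 25),
                            skm = list("5" = c(80.1, 44, 0.012),
                                       "25" = c(99, 27, 0.06)),
                            times = c(0, 30, 90, 180, 330, 500),
                            velocity_noise_frac = 0.002,
                            stress_noise_frac = 0.02,
                            decay_noise = 0.005,
                            dt2_snr = 500) {
  if (missing(seed)) stop("a master seed is required", call. = FALSE)
  seed <- as.integer(seed)
  if (!setequal(names(skm), as.character(applied_rates)))
    stop("skm must have one named entry per applied rate", call. = FALSE)
  cfg <- list(
    seed = seed,
    geometry = list(inner_radius = 10e-3, outer_radius = 11e-3,
                    height = 40e-3, height_assumed = TRUE),
    rheology = list(
      applied_rates = applied_rates, times = times, time_unit = "min",
      skm = skm,
      K = 30, n = 0.47,
      mask_threshold = 0.05, sg_window = 7L, sg_poly_order = 1L,
      velocity_noise_frac = velocity_noise_frac,
      stress_noise_frac = stress_noise_frac,
      velocity_seed = seed + 101L),
    droplet = list(
      before = list(D33 = 3.39, alpha = 0.20),
      after = list(D33 = 4.30, alpha = 0.40),
      D_oil = 4e-12,
      pgse = list(g = seq(0.1, 3, length.out = 32), delta = 2e-3,
                  Delta = 211e-3, delta_assumed = TRUE),
      noise_sigma = decay_noise,
      seed_before = seed + 201L, seed_after = seed + 202L),
    dt2 = list(
      components = data.frame(
        amplitude = c(0.22, 0.78), D = c(9e-10, 4e-12), T2 = c(0.4, 0.12)),
      pgse = list(g = seq(0.1, 6.6, length.out = 32), delta = 1e-3,
                  Delta = 200e-3),
      echo_spacing = 2.2e-3, n_echoes = 256L,
      D_grid = c(1e-13, 1e-8, 64L), T2_grid = c(1e-3, 3, 64L),
      snr = dt2_snr, seed = seed + 301L))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "Pipeline config (seed %d): %d shear times at %s 1/s, droplet D33 %g -> %g um, D-T2 SNR %g\n",
    x$seed, length(x$rheology$times),
    paste(x$rheology$applied_rates, collapse = "/"),
    x$droplet$before$D33, x$droplet$after$D33, x$dt2$snr))
  invisible(x)
}

#' Write and read a pipeline configuration as YAML
#'
#' Serializes the full nested configuration — parameters, grids, noise
#' magnitudes and seeds — so that a run is reproducible from one plain
#' text file.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config_yaml` returns `path` invisibly;
#'   `read_config_yaml` returns the reconstructed `pipeline_config`.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$dt2$components <- as.list(x$dt2$components)
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$seed <- as.integer(x$seed)
  x$dt2$components <- as.data.frame(x$dt2$components)
  for (nm in c("velocity_seed"))
    x$rheology[[nm]] <- as.integer(x$rheology[[nm]])
  x$droplet$seed_before <- as.integer(x$droplet$seed_before)
  x$droplet$seed_after <- as.integer(x$droplet$seed_after)
  x$dt2$seed <- as.integer(x$dt2$seed)
  x$dt2$n_echoes <- as.integer(x$dt2$n_echoes)
  structure(x, class = "pipeline_config")
}

.cfg_geometry <- function(cfg)
  couette_geometry(cfg$geometry$inner_radius, cfg$geometry$outer_radius,
                   cfg$geometry$height)

.cfg_droplet_pgse <- function(cfg)
  pgse_params(cfg$droplet$pgse$g, cfg$droplet$pgse$delta,
              cfg$droplet$pgse$Delta)

.cfg_dt2_pgse <- function(cfg)
  pgse_params(cfg$dt2$pgse$g, cfg$dt2$pgse$delta, cfg$dt2$pgse$Delta)

#' Simulate the full measurement bundle of a pipeline run
#'
#' Forward-simulates every dataset the pipeline consumes under one
#' configuration: Couette velocity profiles with torques at each shearing
#' time (with the yield stress decaying along the structural-kinetic
#' model), before/after PFG droplet decays, and a two-component D-T2
#' surface.  All noise is seeded from the config.
#'
#' @param config A [pipeline_config()].
#' @return List with `rheology` (one entry per applied rate, each holding
#'   `profiles`, `torques`, `yield_radii`), `droplet_before`,
#'   `droplet_after` ([pfg_decay()]), and `dt2` ([dt2_dataset()]).
#' @export
simulate_measurements <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  geom <- .cfg_geometry(config)
  rh <- config$rheology

  rheo <- list()
  for (k in seq_along(rh$applied_rates)) {
    rate <- rh$applied_rates[k]
    sk <- rh$skm[[as.character(rate)]]
    rotor <- rotor_rate_from_applied(rate, geom)
    v_sigma <- rh$velocity_noise_frac * rotor * geom$inner_radius
    profiles <- list(); torques <- numeric(0); yr <- numeric(0)
    for (i in seq_along(rh$times)) {
      tau0_t <- skm_model(skm_params(sk[1], sk[2], sk[3]), rh$times[i])
      sol <- couette_forward_solve(
        geom, hb_params(tau0_t, rh$K, rh$n), rotor)
      prof <- sol$profile
      prof$time_stamp <- rh$times[i]
      if (v_sigma > 0)
        prof <- noisy_profile(
          prof, noise_spec(v_sigma, rh$velocity_seed + 100L * k + i,
                           "additive"))
      profiles[[i]] <- prof
      torques[i] <- sol$torque
      yr[i] <- if (is.na(sol$yield_radius)) NA_real_ else sol$yield_radius
    }
    rheo[[as.character(rate)]] <- list(profiles = profiles,
                                       torques = torques,
                                       yield_radii = yr)
  }

  dp <- .cfg_droplet_pgse(config)
  before <- pfg_decay_lognormal(
    config$droplet$before$D33, config$droplet$before$alpha,
    config$droplet$D_oil, dp,
    noise = noise_spec(config$droplet$noise_sigma,
                       config$droplet$seed_before, "additive"))
  after <- pfg_decay_lognormal(
    config$droplet$after$D33, config$droplet$after$alpha,
    config$droplet$D_oil, dp,
    noise = noise_spec(config$droplet$noise_sigma,
                       config$droplet$seed_after, "additive"))

  d2 <- config$dt2
  echo_times <- d2$echo_spacing * seq_len(d2$n_echoes)
  s00 <- sum(d2$components$amplitude)
  dt2 <- dt2_signal(d2$components, .cfg_dt2_pgse(config), echo_times,
                    noise = noise_spec(s00 / d2$snr, d2$seed, "additive"))

  list(rheology = rheo, droplet_before = before, droplet_after = after,
       dt2 = dt2)
}

#' Write a complete seeded fixture bundle to disk
#'
#' Emits every simulated dataset of [simulate_measurements()] in the
#' package's CSV schemas: per-time velocity profiles, a torque series, the
#' two PFG decays and the D-T2 bundle.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
write_fixture_bundle <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_measurements(config)
  files <- character(0)
  for (rate in names(sim$rheology)) {
    rr <- sim$rheology[[rate]]
    for (i in seq_along(rr$profiles)) {
      f <- file.path(dir, sprintf("profile_rate%s_t%03d.csv", rate, i))
      write_profile_csv(rr$profiles[[i]], f)
      files <- c(files, f)
    }
    tq <- file.path(dir, sprintf("torques_rate%s.csv", rate))
    .write_csv_exact(data.frame(t_min = config$rheology$times,
                                torque_Nm = rr$torques), tq)
    files <- c(files, tq)
  }
  db <- file.path(dir, "droplet_before.csv")
  da <- file.path(dir, "droplet_after.csv")
  write_decay_csv(sim$droplet_before, db)
  write_decay_csv(sim$droplet_after, da)
  stem <- file.path(dir, "dt2")
  write_dt2_csv(sim$dt2, stem)
  invisible(c(files, db, da, paste0(stem, c("_signal.csv",
                                                "_gradients.csv",
                                                "_echoes.csv",
                                                "_pgse.json"))))
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the requested stages in dependency order against simulated
#' measurements from the given configuration, writing each stage's outputs
#' under `out_dir` and returning a manifest.
#'
#' Stages: `"rheology"` (simulate profiles -> shear rates -> local flow
#' curves -> global-n Herschel-Bulkley fits -> structural-kinetic fit of
#' the yield-stress series), `"droplet"` (simulate PFG decays -> lognormal
#' size fits -> growth ratio), `"dt2"` (simulate decay surface -> 2D
#' inverse Laplace map -> water-peak extraction).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (default all; an empty
#'   vector yields a manifest with no outputs).
#' @return An object of class `run_manifest`: config hash, package
#'   version, per-stage status and file lists, timestamps, and the fitted
#'   objects in `$results`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("rheology", "droplet", "dt2")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(stages))
    stages <- match.arg(stages, c("rheology", "droplet", "dt2"),
                        several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   package_version =
                     as.character(utils::packageVersion("emulsionrheo")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list(), results = list())
  sim <- if (length(stages)) simulate_measurements(config) else NULL
  geom <- .cfg_geometry(config)

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       message = conditionMessage(res),
                                       files = character(0))
    } else {
      manifest$stages[[name]] <<- list(status = "ok", files = res$files)
      manifest$results[[name]] <<- res$value
    }
  }

  if ("rheology" %in% stages) run_stage("rheology", function() {
    rh <- config$rheology
    files <- character(0)
    lfcs <- list(); rate_of <- character(0)
    for (rate in names(sim$rheology)) {
      rr <- sim$rheology[[rate]]
      for (i in seq_along(rr$profiles)) {
        lfc <- assemble_lfc(rr$profiles[[i]], rr$torques[i], geom,
                            mask_threshold = rh$mask_threshold,
                            window = rh$sg_window,
                            poly_order = rh$sg_poly_order)
        f <- file.path(out_dir, sprintf("lfc_rate%s_t%03d.csv", rate, i))
        write_lfc_csv(lfc, f)
        files <- c(files, f)
        lfcs <- c(lfcs, list(lfc)); rate_of <- c(rate_of, rate)
      }
    }
    # one flow index shared across all rates and shearing times
    gfit <- fit_hb_global_n(lfcs)
    skm_fits <- list(); jlist <- list(shared_n = gfit$n)
    for (rate in names(sim$rheology)) {
      sel <- rate_of == rate
      series <- gfit$yield_stress_series[sel, ]
      sf <- file.path(out_dir, sprintf("yield_stress_rate%s.csv", rate))
      write_series_csv(series, sf)
      w <- if (all(is.finite(series$tau0_se)) && all(series$tau0_se > 0))
        1 / series$tau0_se^2 else NULL
      skm <- fit_skm(series$time, series$tau0, weights = w,
                     time_unit = rh$time_unit)
      skm_fits[[rate]] <- skm
      jlist[[paste0("rate_", rate)]] <-
        list(tau00_Pa = skm$params$tau00, tau0e_Pa = skm$params$tau0e,
             ks = skm$params$ks, ks_unit = paste0("1/", rh$time_unit),
             breakdown_ratio = skm$breakdown_ratio, flags = skm$flags)
      files <- c(files, sf)
    }
    jf <- file.path(out_dir, "skm_fit.json")
    jsonlite::write_json(jlist, jf, auto_unbox = TRUE, digits = NA)
    list(files = c(files, jf),
         value = list(lfcs = lfcs, rate_of = rate_of, global_fit = gfit,
                      skm_fits = skm_fits))
  })

  if ("droplet" %in% stages) run_stage("droplet", function() {
    dp <- .cfg_droplet_pgse(config)
    before <- fit_droplet_size(sim$droplet_before, dp,
                               D_oil = config$droplet$D_oil)
    after <- fit_droplet_size(sim$droplet_after, dp,
                              D_oil = config$droplet$D_oil)
    jf <- file.path(out_dir, "droplet_size.json")
    jsonlite::write_json(
      list(before = list(D33_um = before$D33, alpha = before$alpha),
           after = list(D33_um = after$D33, alpha = after$alpha),
           growth_ratio = growth_ratio(after, before)),
      jf, auto_unbox = TRUE, digits = NA)
    list(files = jf,
         value = list(before = before, after = after,
                      growth_ratio = growth_ratio(after, before)))
  })

  if ("dt2" %in% stages) run_stage("dt2", function() {
    d2 <- config$dt2
    map <- ilt2d(sim$dt2,
                 D_grid = log_grid(d2$D_grid[1], d2$D_grid[2],
                                   d2$D_grid[3]),
                 T2_grid = log_grid(d2$T2_grid[1], d2$T2_grid[2],
                                    d2$T2_grid[3]))
    wp <- extract_water_peak(map)
    mf <- file.path(out_dir, "dt2_map.csv")
    utils::write.table(
      matrix(sprintf("%.8g", map$amplitude), nrow = nrow(map$amplitude)),
      mf, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
    jf <- file.path(out_dir, "dt2_peaks.json")
    jsonlite::write_json(
      list(reg_weight = map$reg_weight,
           water_peak = list(D_m2_per_s = wp$D, T2_s = wp$T2,
                             mass = wp$mass),
           peaks = map$peaks),
      jf, auto_unbox = TRUE, digits = NA)
    list(files = c(mf, jf), value = list(map = map, water_peak = wp))
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    manifest[c("config_hash", "package_version", "started", "finished",
               "stages")],
    mf, auto_unbox = TRUE, digits = NA)
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run %s (package %s)\n", x$config_hash,
              x$package_version))
  for (nm in names(x$stages))
    cat(sprintf("  %s: %s (%d file(s))\n", nm, x$stages[[nm]]$status,
                length(x$stages[[nm]]$files)))
  invisible(x)
}
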