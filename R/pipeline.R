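#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end analysis: which xylitol groups to
#' emulate, the sampling schedule, measurement noise, slab geometry,
#' estimator and simulator options, the seed, and an optional output
#' directory. `read_run_config()` loads the same structure from YAML.
#'
#' @param groups character vector of xylitol groups.
#' @param schedule sampling times, hours.
#' @param replicates records per timepoint.
#' @param noise_sd relative measurement noise s.d.
#' @param seed integer master seed; per-group generator seeds are derived
#'   from it deterministically.
#' @param thickness_L slab thickness along the diffusion axis, metres.
#' @param slice_times slice-profile sampling times, hours.
#' @param slice_mode forward model for slice profiles
#'   (see [generate_slice_profiles()]).
#' @param sim_group group whose De drives the slab simulation.
#' @param sim_hours simulated duration, hours.
#' @param sim_dx 1D grid spacing, metres.
#' @param sim_dt time step, seconds.
#' @param error_tolerance_pct flag threshold for profile validation, percent.
#' @param outdir output directory for CSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(groups = c("0%", "4%", "8%", "12%"),
                       schedule = seq(0, 24, by = 2), replicates = 3,
                       noise_sd = 0.02, seed = 1, thickness_L = 0.01,
                       slice_times = c(6, 12, 24),
                       slice_mode = "semi_infinite",
                       sim_group = "4%", sim_hours = 12,
                       sim_dx = 2.5e-4, sim_dt = 60,
                       error_tolerance_pct = 15, outdir = NULL) {
  stopifnot(all(groups %in% c("0%", "4%", "8%", "12%")),
            sim_group %in% groups, length(schedule) >= 3)
  structure(list(groups = groups, schedule = schedule, replicates = replicates,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 thickness_L = thickness_L, slice_times = slice_times,
                 slice_mode = slice_mode, sim_group = sim_group,
                 sim_hours = sim_hours, sim_dx = sim_dx, sim_dt = sim_dt,
                 error_tolerance_pct = error_tolerance_pct, outdir = outdir),
            class = "run_config")
}

#' @param path YAML file with fields named as the `run_config()` arguments.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_brinesim(paste("unknown config fields:", paste(unknown, collapse = ", ")),
                  "invalid_config")
  do.call(run_config, vals)
}

group_seed <- function(cfg, i) (cfg$seed + 1009L * i) %% .Machine$integer.max

#' Run the full curing analysis pipeline
#'
#' One call through every stage: synthetic data generation per group,
#' square-root kinetic fits for the three change variables, the three
#' time-variant models for the aqueous salt content (plus the joint
#' shared-exponent power fit across groups), effective-diffusivity
#' estimation by all three methods, a one-face 1D slab simulation for the
#' configured group, and validation of the simulated slice profile against
#' the synthetic observations. When `cfg$outdir` is set, measurement and
#' slice CSVs and a machine-readable JSON summary are written there.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return the summary, invisibly: a nested list with one entry per group
#'   (kinetic fits, time-model fits, De estimates), the joint power fit,
#'   the simulation summary and the validation report.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  log_line <- function(...) if (!quiet) message(sprintf(...))
  summary <- list(groups = list())
  z_groups <- list()

  for (i in seq_along(cfg$groups)) {
    g <- cfg$groups[i]
    seed_g <- group_seed(cfg, i)
    log_line("[generate] group %s (seed %d)", g, seed_g)
    gt <- curing_ground_truth(g, noise_sd = cfg$noise_sd, seed = seed_g)
    series <- generate_curing_series(gt, schedule = cfg$schedule,
                                     replicates = cfg$replicates)

    log_line("[fit] group %s: kinetics, time models, slope-method De", g)
    fits <- fit_group_measurements(series$records, group = g,
                                   thickness_L = cfg$thickness_L)
    z_groups[[g]] <- fits$z_series

    log_line("[estimate-de] group %s: erf-profile and model-implied De", g)
    profs <- generate_slice_profiles(gt, times = cfg$slice_times,
                                     mode = cfg$slice_mode, seed = seed_g + 1L)
    de_erf <- erf_profile_method(profs[[length(profs)]], cs = 0.08,
                                 c0 = gt$meat0$salt_frac)
    de_model <- de_from_time_model(fits$time_models$power, fits$equilibrium,
                                   thickness_L = cfg$thickness_L,
                                   grid = c(0, fits$z_series$times))

    summary$groups[[g]] <- list(
      kinetics = lapply(fits$kinetics, unclass),
      time_models = lapply(fits$time_models, unclass),
      best_model = fits$best_model,
      de = list(slope = unclass(fits$de_slope), erf_profile = unclass(de_erf),
                from_time_model = unclass(de_model)))

    if (!is.null(cfg$outdir)) {
      dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
      write_measurements_csv(series,
        file.path(cfg$outdir, sprintf("measurements_%s.csv", gsub("%", "pct", g))))
      write_slices_csv(profs, g,
        file.path(cfg$outdir, sprintf("slices_%s.csv", gsub("%", "pct", g))))
    }
  }

  if (length(cfg$groups) >= 2) {
    log_line("[time-models] joint shared-exponent power fit")
    joint <- fit_power_joint(z_groups)
    summary$joint_power <- list(shared_b = attr(joint, "shared_b"),
                                fits = lapply(joint, unclass))
  }

  log_line("[simulate] group %s, %g h one-face slab", cfg$sim_group, cfg$sim_hours)
  gt_sim <- curing_ground_truth(cfg$sim_group, noise_sd = cfg$noise_sd,
                                seed = group_seed(cfg, match(cfg$sim_group, cfg$groups)))
  scfg <- sim_config(de = gt_sim$de, boundary_mode = "one_face",
                     boundary_value = 0.08, initial_value = gt_sim$meat0$salt_frac,
                     duration = cfg$sim_hours * 3600, time_step = cfg$sim_dt)
  fld <- solve_slab_1d(scfg, gt_sim$geometry, dx = cfg$sim_dx)[[1]]
  sim_slices <- field_to_slices(fld)
  pen <- penetration_depth(fld, 0.01)
  summary$simulation <- list(group = cfg$sim_group, de = gt_sim$de,
                             hours = cfg$sim_hours,
                             penetration_depth_m = pen,
                             slice_centers_m = sim_slices$slice_centers,
                             slice_salt_frac = sim_slices$salt_frac)

  log_line("[validate] simulated vs observed slice profile")
  obs <- generate_slice_profiles(gt_sim, times = cfg$sim_hours, mode = "slab",
                                 seed = group_seed(cfg, match(cfg$sim_group, cfg$groups)) + 2L)
  rep_val <- validate_against_profiles(list(sim_slices), slices_to_df(obs, cfg$sim_group),
                                       tolerance_pct = cfg$error_tolerance_pct)
  summary$validation <- rep_val

  if (!is.null(cfg$outdir)) {
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("[done] summary written to %s", file.path(cfg$outdir, "summary.json"))
  }
  invisible(summary)
}

#' Fit every per-group model to raw measurement records
#'
#' The per-group analysis stage shared by [run_pipeline()] and the command
#' line: square-root kinetic fits for the total/water/salt change
#' variables, the aqueous-salt trajectory Z(t) from replicate-averaged
#' compositions, the three time-variant model fits (ranked by R^2), the
#' equilibrium aqueous salt content implied by the brine specification
#' (8% w/w NaCl, meat:brine 1:4, xylitol per group), and the slope-method
#' diffusivity from the driving-force series.
#'
#' @param records a data frame with columns `replicate`, `time_h`,
#'   `mass_g`, `moisture_frac`, `salt_frac`, including t = 0 rows.
#' @param group xylitol group label (sets the brine xylitol fraction).
#' @param thickness_L slab thickness, metres.
#' @return a list: `kinetics` (3 fits), `z_series`, `time_models` (3 fits),
#'   `best_model`, `equilibrium` (an [equilibrium_state()]), `de_slope`.
#' @export
fit_group_measurements <- function(records, group = "0%", thickness_L = 0.01) {
  need <- c("time_h", "mass_g", "moisture_frac", "salt_frac")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop_brinesim(paste("records lack column(s):", paste(missing, collapse = ", ")),
                  "schema_mismatch")
  if (!any(records$time_h == 0))
    stop_brinesim("records need a t = 0 baseline", "schema_mismatch")
  kin <- lapply(c(total = "total", water = "water", salt = "salt"),
                function(v) fit_sqrt_kinetics(change_series_from_records(records, v)))
  agg <- stats::aggregate(records[c("mass_g", "moisture_frac", "salt_frac")],
                          by = list(time_h = records$time_h), FUN = mean)
  agg <- agg[order(agg$time_h), ]
  z <- aqueous_salt_fraction(agg$salt_frac, agg$moisture_frac)
  zt <- agg$time_h
  tm <- lapply(c(linear = "linear", power = "power", exponential = "exponential"),
               function(f) fit_time_model(f, zt, z))
  base <- agg[agg$time_h == 0, ]
  meat0 <- composition_record(0, base$mass_g, base$moisture_frac, base$salt_frac)
  xyl <- .gt_tables$xylitol[match(group, .gt_tables$groups)]
  brine <- brine_spec(mass = 4 * base$mass_g, salt_frac = 0.08,
                      water_frac = 0.92 - xyl, xylitol_frac = xyl)
  ze <- equilibrium_aqueous_salt(meat0, brine)
  z0 <- aqueous_salt_fraction(base$salt_frac, base$moisture_frac)
  omy <- driving_force_complement(z, yt = ze, z0 = z0, ze = ze)
  list(kinetics = kin, z_series = list(times = zt[zt > 0], z = z[zt > 0]),
       time_models = tm, best_model = rank_models(tm)[[1]]$form,
       equilibrium = equilibrium_state(z0, ze),
       de_slope = slope_method(zt, omy, thickness_L))
}

#' Validate simulated slice profiles against observations
#'
#' Matches each simulated profile to the observed profile at the same time
#' and reports the mean absolute relative error per time, flagging times
#' whose error exceeds the tolerance.
#'
#' @param simulated a list of [slice_profile()]s.
#' @param observed a data frame (or CSV path) with columns `time_h`,
#'   `slice_center_m`, `salt_frac`.
#' @param tolerance_pct flag threshold, percent.
#' @return a data frame with columns `time_h`, `error_pct`, `flagged`.
#' @export
validate_against_profiles <- function(simulated, observed, tolerance_pct = 15) {
  if (is.character(observed)) observed <- utils::read.csv(observed)
  need <- c("time_h", "slice_center_m", "salt_frac")
  missing <- setdiff(need, names(observed))
  if (length(missing))
    stop_brinesim(paste("observed data lacks column(s):",
                        paste(missing, collapse = ", ")), "schema_mismatch")
  out <- do.call(rbind, lapply(simulated, function(sp) {
    sub <- observed[abs(observed$time_h - sp$time) < 1e-9, ]
    if (nrow(sub) == 0)
      stop_brinesim(sprintf("no observed profile at t = %g h", sp$time),
                    "schema_mismatch")
    sub <- sub[order(sub$slice_center_m), ]
    op <- slice_profile(sp$time, sub$slice_center_m, sub$salt_frac,
                        sp$slice_thickness, unit = sp$unit %||% "fraction")
    err <- profile_relative_error(sp, op)
    data.frame(time_h = sp$time, error_pct = err,
               flagged = err > tolerance_pct)
  }))
  rownames(out) <- NULL
  out
}

# --- CSV schemas ------------------------------------------------------------

#' Read and write the pipeline's CSV schemas
#'
#' Measurements: `group, replicate, time_h, mass_g, moisture_frac,
#' salt_frac`. Slices: `group, time_h, slice_center_m, salt_frac`.
#'
#' @param series a `"curing_series"`.
#' @param path file path.
#' @return readers return data frames; writers return the path invisibly.
#' @export
write_measurements_csv <- function(series, path) {
  df <- cbind(group = series$group, series$records)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("group", "replicate", "time_h", "mass_g", "moisture_frac", "salt_frac")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_brinesim(paste("measurements file lacks column(s):",
                        paste(missing, collapse = ", ")), "schema_mismatch")
  df
}

slices_to_df <- function(profiles, group) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(group = group, time_h = p$time,
               slice_center_m = p$slice_centers, salt_frac = p$salt_frac)))
}

#' @param profiles a list of [slice_profile()]s.
#' @param group group label written alongside.
#' @rdname write_measurements_csv
#' @export
write_slices_csv <- function(profiles, group, path) {
  utils::write.csv(slices_to_df(profiles, group), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_slices_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("group", "time_h", "slice_center_m", "salt_frac")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_brinesim(paste("slices file lacks column(s):",
                        paste(missing, collapse = ", ")), "schema_mismatch")
  df
}
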