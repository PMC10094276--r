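# Ground-truth parameter sets for the emulated curing experiment: per-group
# sqrt-time kinetic coefficients, time-variant model parameters, and the
# one-way (single-exposed-face) effective diffusivities. Initial tissue
# composition: 10 g slabs at 74% moisture with 0.41% NaCl, chosen so the
# initial aqueous salt fraction matches the power-model offset (~0.0055).
.gt_tables <- list(
  groups = c("0%", "4%", "8%", "12%"),
  xylitol = c(0, 0.04, 0.08, 0.12),
  de_one_way = c(1.29e-9, 1.22e-9, 1.20e-9, 1.15e-9),
  kinetics = list(
    total = list(k1 = c(0.94972, 0.95896, 0.98067, 0.96797),
                 k2 = c(0.066870, 0.056627, 0.047707, 0.032758)),
    water = list(k1 = c(0.95202, 0.97873, 0.98555, 0.97978),
                 k2 = c(0.060436, 0.047178, 0.036387, 0.029523)),
    salt  = list(k1 = c(0.99072, 0.99204, 0.99316, 0.99345),
                 k2 = c(0.010715, 0.009633, 0.008951, 0.008060))),
  power = list(A = c(0.026587, 0.025606, 0.024312, 0.022290),
               b = rep(0.212376, 4),
               c = c(0.005467, 0.005471, 0.005456, 0.005470)),
  linear = list(A = c(0.0014143, 0.0013564, 0.0013992, 0.0013282),
                b = c(0.0294540, 0.028745, 0.0280392, 0.0262829)),
  exponential = list(A = c(0.053269, 0.051846, 0.0523298, 0.04943),
                     b = c(0.408018, 0.3930302, 0.3473287, 0.33598))
)

#' Ground truth for the synthetic curing experiment
#'
#' Assembles the known-parameter description of one experimental group from
#' which the generators draw: the square-root kinetic parameters for total
#' weight, moisture and salt change, the time-variant model parameters for
#' the aqueous salt content, the one-way effective diffusivity, the brine
#' specification (8% w/w NaCl, meat:brine 1:4, xylitol per group), the
#' slab geometry and the measurement-noise level.
#'
#' @param group xylitol group, one of `"0%"`, `"4%"`, `"8%"`, `"12%"`.
#' @param noise_sd relative (multiplicative) measurement noise s.d.;
#'   default 2%.
#' @param seed integer seed for the generators, or `NULL`.
#' @param m0 initial sample mass, g.
#' @param x0w,x0s initial moisture and salt mass fractions of the tissue.
#' @return an object of class `"ground_truth"`.
#' @examples
#' gt <- curing_ground_truth("0%")
#' gt$de
#' @export
curing_ground_truth <- function(group = c("0%", "4%", "8%", "12%"),
                                noise_sd = 0.02, seed = NULL,
                                m0 = 10, x0w = 0.74, x0s = 0.0041) {
  group <- match.arg(group)
  if (noise_sd < 0) stop_brinesim("noise_sd must be >= 0", "invalid_ground_truth")
  i <- match(group, .gt_tables$groups)
  xyl <- .gt_tables$xylitol[i]
  kin <- lapply(.gt_tables$kinetics, function(v)
    list(k1 = v$k1[i], k2 = v$k2[i]))
  meat0 <- composition_record(0, m0, moisture_frac = x0w, salt_frac = x0s)
  brine <- brine_spec(mass = 4 * m0, salt_frac = 0.08,
                      water_frac = 0.92 - xyl, xylitol_frac = xyl)
  structure(list(
    group = group, xylitol_frac = xyl, de = .gt_tables$de_one_way[i],
    kinetics = kin,
    power = list(A = .gt_tables$power$A[i], b = .gt_tables$power$b[i],
                 c = .gt_tables$power$c[i]),
    linear = list(A = .gt_tables$linear$A[i], b = .gt_tables$linear$b[i]),
    exponential = list(A = .gt_tables$exponential$A[i],
                       b = .gt_tables$exponential$b[i]),
    meat0 = meat0, brine = brine, geometry = slab_geometry(),
    noise_sd = noise_sd, seed = seed), class = "ground_truth")
}

# multiplicative Gaussian noise truncated at physical bounds
noisy <- function(x, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(x)
  pmin(upper, pmax(lower, x * (1 + stats::rnorm(length(x), 0, sd))))
}

#' Generate a synthetic curing time series
#'
#' Emulates the sampling design of the curing experiment: triplicate slabs
#' removed every 2 h over 24 h, each weighed and assayed for moisture and
#' NaCl. Masses follow the square-root kinetic law
#' y(t) = k1 + k2 sqrt(t) in relative-mass form for total weight, water
#' and salt; the moisture and salt fractions are reconstructed from the
#' implied component masses, so the percent-change equations invert the
#' construction exactly. Measurement noise is multiplicative Gaussian,
#' truncated at physical bounds; at t = 0 the true initial composition is
#' reported (the kinetic lines describe t > 0).
#'
#' @param gt a [curing_ground_truth()].
#' @param schedule sampling times in hours, increasing, starting at 0.
#' @param replicates records per timepoint.
#' @param noise_sd,seed override the ground truth's noise level and seed.
#' @return an object of class `"curing_series"`: the ground-truth handles
#'   plus a `records` data frame with columns `replicate`, `time_h`,
#'   `mass_g`, `moisture_frac`, `salt_frac`.
#' @export
generate_curing_series <- function(gt, schedule = seq(0, 24, by = 2),
                                   replicates = 3, noise_sd = gt$noise_sd,
                                   seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"))
  if (any(diff(schedule) <= 0) || any(schedule < 0))
    stop_brinesim("schedule must be increasing and non-negative", "invalid_ground_truth")
  m0 <- gt$meat0$mass; x0w <- gt$meat0$moisture_frac; x0s <- gt$meat0$salt_frac
  k <- gt$kinetics
  true_state <- function(t) {
    if (t == 0) return(c(m0, x0w, x0s))
    M <- m0 * kinetic_line(k$total$k1, k$total$k2, t)
    W <- m0 * (x0w + kinetic_line(k$water$k1, k$water$k2, t) - 1)
    S <- m0 * (x0s + kinetic_line(k$salt$k1, k$salt$k2, t) - 1)
    if (M <= 0 || W < 0 || S < 0)
      stop_brinesim("kinetic parameters imply non-physical masses", "invalid_ground_truth")
    c(M, W / M, S / M)
  }
  rows <- with_seed(seed, {
    do.call(rbind, lapply(schedule, function(t) {
      s <- true_state(t)
      do.call(rbind, lapply(seq_len(replicates), function(r) {
        mass <- noisy(s[1], noise_sd, lower = 1e-6)
        xw <- noisy(s[2], noise_sd, upper = 1)
        xs <- noisy(s[3], noise_sd, upper = 1)
        if (xw + xs > 1) { sc <- 1 / (xw + xs); xw <- xw * sc; xs <- xs * sc }
        data.frame(replicate = r, time_h = t, mass_g = mass,
                   moisture_frac = xw, salt_frac = xs)
      }))
    }))
  })
  structure(list(group = gt$group, xylitol_frac = gt$xylitol_frac,
                 brine = gt$brine, geometry = gt$geometry,
                 meat0 = gt$meat0, records = rows, schedule = schedule),
            class = "curing_series")
}

#' Percent-change series from raw curing records
#'
#' Averages replicates per timepoint and forms the signed percent change of
#' the chosen variable against the t = 0 baseline.
#'
#' @param series a `"curing_series"` from [generate_curing_series()], or a
#'   bare records data frame with the same columns.
#' @param variable `"total"`, `"water"`, or `"salt"`.
#' @param drop_t0 omit the t = 0 baseline point from the returned series
#'   (the kinetic law describes t > 0; the baseline itself is exactly 0).
#' @return a [change_series()].
#' @export
change_series_from_records <- function(series,
                                       variable = c("total", "water", "salt"),
                                       drop_t0 = FALSE) {
  variable <- match.arg(variable)
  rec <- if (is.data.frame(series)) series else series$records
  agg <- stats::aggregate(rec[c("mass_g", "moisture_frac", "salt_frac")],
                          by = list(time_h = rec$time_h), FUN = mean)
  agg <- agg[order(agg$time_h), ]
  base <- agg[agg$time_h == min(agg$time_h), ]
  delta <- switch(variable,
    total = weight_change(agg$mass_g, base$mass_g),
    water = component_change(agg$mass_g, agg$moisture_frac,
                             base$mass_g, base$moisture_frac),
    salt  = component_change(agg$mass_g, agg$salt_frac,
                             base$mass_g, base$salt_frac))
  if (min(agg$time_h) == 0) delta[agg$time_h == 0] <- 0
  if (drop_t0) {
    keep <- agg$time_h > 0
    return(change_series(variable, agg$time_h[keep], delta[keep]))
  }
  change_series(variable, agg$time_h, delta)
}

#' Generate slice-resolved salt profiles
#'
#' Emulates the one-way (paraffin-sealed, single exposed face) sectioning
#' assay: the depth profile of salt at given times, reported per 2 mm
#' slice. In `"semi_infinite"` mode the profile is the analytic erf
#' solution evaluated at the slice centres (the idealisation under which
#' the erf-inversion estimator is exact); in `"slab"` mode the
#' finite-difference solver is run on the 10 mm slab and slice averages
#' are taken, which includes the sealed-face reflection real samples show
#' at long times.
#'
#' @param gt a [curing_ground_truth()].
#' @param times sampling times, hours.
#' @param slice_thickness metres.
#' @param mode `"semi_infinite"` or `"slab"`.
#' @param cs,c0 boundary and initial salt content (mass fractions).
#' @param noise_sd,seed override the ground truth's values.
#' @return a list of [slice_profile()]s, one per time.
#' @export
generate_slice_profiles <- function(gt, times = c(6, 12, 24),
                                    slice_thickness = 0.002,
                                    mode = c("semi_infinite", "slab"),
                                    cs = 0.08, c0 = gt$meat0$salt_frac,
                                    noise_sd = gt$noise_sd, seed = gt$seed) {
  mode <- match.arg(mode)
  stopifnot(inherits(gt, "ground_truth"), all(times >= 0))
  L <- gt$geometry$lengths[3]
  centers <- seq(slice_thickness / 2, L - slice_thickness / 2,
                 by = slice_thickness)
  profs <- lapply(times, function(t) {
    if (t == 0) {
      vals <- rep(c0, length(centers))
    } else if (mode == "semi_infinite") {
      vals <- analytic_profile(centers, t * 3600, gt$de, cs = cs, c0 = c0)
    } else {
      cfg <- sim_config(de = gt$de, boundary_mode = "one_face",
                        boundary_value = cs, initial_value = c0,
                        duration = t * 3600, time_step = 60)
      fld <- solve_slab_1d(cfg, gt$geometry)[[1]]
      vals <- field_to_slices(fld, slice_thickness)$salt_frac
    }
    slice_profile(t, centers, vals, slice_thickness)
  })
  with_seed(seed, lapply(profs, function(p) {
    p$salt_frac <- noisy(p$salt_frac, noise_sd, upper = 1)
    p
  }))
}

#' Generate an aqueous-salt time series
#'
#' Evaluates one of the ground truth's time-variant models for the
#' aqueous-phase NaCl content on a sampling schedule, with multiplicative
#' measurement noise, producing the input shape the time-model fitters
#' consume.
#'
#' @param gt a [curing_ground_truth()].
#' @param schedule sampling times, hours.
#' @param form which ground-truth model to sample from.
#' @param noise_sd,seed override the ground truth's values.
#' @return a list with `times` (hours) and `z` (aqueous salt fractions).
#' @export
generate_z_series <- function(gt, schedule = seq(2, 24, by = 2),
                              form = c("power", "linear", "exponential"),
                              noise_sd = gt$noise_sd, seed = gt$seed) {
  form <- match.arg(form)
  stopifnot(inherits(gt, "ground_truth"))
  p <- gt[[form]]
  z <- switch(form,
              power = p$A * schedule^p$b + p$c,
              linear = p$A * schedule + p$b,
              exponential = p$A * (1 - exp(-p$b * schedule)))
  z <- with_seed(seed, noisy(z, noise_sd, upper = 1))
  list(times = schedule, z = z)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth, %s xylitol: De = %.3g m^2 s^-1, salt k2 = %.6g h^-0.5, noise sd = %g\n",
              x$group, x$de, x$kinetics$salt$k2, x$noise_sd))
  invisible(x)
}
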