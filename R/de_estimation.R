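#' Effective-diffusivity estimate container
#'
#' @param de effective diffusion coefficient, m^2 s^-1 (> 0).
#' @param intercept_K intercept of the slope-method regression (NA for
#'   methods without one).
#' @param r2 coefficient of determination of the underlying fit.
#' @param method one of `"slope"`, `"erf_profile"`, `"from_time_model"`.
#' @param n_points number of points (timepoints or slices) used.
#' @param excluded number of slices excluded as unusable (erf method).
#' @return an object of class `"de_estimate"`.
#' @export
de_estimate <- function(de, intercept_K = NA_real_, r2 = NA_real_,
                        method = c("slope", "erf_profile", "from_time_model"),
                        n_points, excluded = 0L) {
  method <- match.arg(method)
  if (!is.finite(de) || de <= 0)
    stop_brinesim("estimated De must be positive and finite", "invalid_de")
  stopifnot(n_points >= 1)
  structure(list(de = de, intercept_K = intercept_K, r2 = r2, method = method,
                 n_points = as.integer(n_points), excluded = as.integer(excluded)),
            class = "de_estimate")
}

#' @export
print.de_estimate <- function(x, ...) {
  cat(sprintf("De = %.4g m^2 s^-1 (%s method, n = %d%s%s)\n",
              x$de, x$method, x$n_points,
              if (is.finite(x$intercept_K)) sprintf(", K = %.4g", x$intercept_K) else "",
              if (x$excluded > 0) sprintf(", %d slices excluded", x$excluded) else ""))
  invisible(x)
}

#' Slope-method estimate of the effective diffusion coefficient
#'
#' For an isothermal semi-infinite slab with unidirectional mass transfer,
#' the short-time solution of Fick's second law makes the driving-force
#' complement linear in the square root of time,
#' \deqn{1 - Y(t) = \frac{2}{L}\sqrt{\frac{D_e t}{\pi}} + K,}
#' so a least-squares fit of 1 - Y on sqrt(t) yields
#' De = pi (s L / 2)^2 from the slope s. Time is converted to seconds
#' internally so De comes out in m^2 s^-1.
#'
#' @param times observation times; hours by default (see `time_unit`).
#' @param one_minus_Y driving-force complements (see
#'   [driving_force_complement()]).
#' @param thickness_L slab thickness along the diffusion axis, metres. Use
#'   the full thickness for a single exposed face (paraffin-sealed sides)
#'   and half the thickness for two-sided exposure.
#' @param time_unit `"hours"` or `"seconds"`.
#' @return a [de_estimate()] with `method = "slope"`.
#' @examples
#' t <- seq(2, 24, by = 2)
#' y <- (2 / 0.01) * sqrt(2.58e-9 * t * 3600 / pi) - 0.1060
#' slope_method(t, y, thickness_L = 0.01)
#' @export
slope_method <- function(times, one_minus_Y, thickness_L,
                         time_unit = c("hours", "seconds")) {
  time_unit <- match.arg(time_unit)
  if (thickness_L <= 0) stop_brinesim("thickness must be positive", "invalid_geometry")
  if (length(unique(times)) < 3)
    stop_brinesim("need at least 3 distinct timepoints", "insufficient_data")
  ts <- if (time_unit == "hours") times * 3600 else times
  fit <- stats::lm(one_minus_Y ~ I(sqrt(ts)))
  cf <- unname(coef(fit))
  s <- cf[2]
  if (s <= 0)
    stop_brinesim("fitted slope is not positive: no salt uptake detected",
                  "invalid_direction")
  de_estimate(de = pi * (s * thickness_L / 2)^2, intercept_K = cf[1],
              r2 = r_squared(one_minus_Y, stats::fitted(fit)),
              method = "slope", n_points = length(times))
}

#' Slice-resolved salt profile
#'
#' Salt content versus depth at one sampling time, for a one-way (single
#' exposed face) slab sectioned into slices orthogonal to the transfer
#' direction. Depth 0 is the exposed face.
#'
#' @param time sampling time, hours.
#' @param slice_centers slice-centre depths, metres, strictly increasing.
#' @param salt_frac salt mass fraction per slice.
#' @param slice_thickness slice thickness, metres.
#' @param unit `"fraction"` (mass fraction, validated to \[0, 1\]) or
#'   `"molar"` (mol m^-3, for simulation fields on the molar scale).
#' @return an object of class `"slice_profile"`.
#' @export
slice_profile <- function(time, slice_centers, salt_frac,
                          slice_thickness = 0.002,
                          unit = c("fraction", "molar")) {
  unit <- match.arg(unit)
  stopifnot(length(slice_centers) == length(salt_frac))
  if (any(diff(slice_centers) <= 0))
    stop_brinesim("slice centres must be strictly increasing", "invalid_profile")
  if (unit == "fraction" && any(salt_frac < 0 | salt_frac > 1))
    stop_brinesim("slice salt fractions must be in [0, 1]", "invalid_profile")
  structure(list(time = time, slice_centers = slice_centers,
                 salt_frac = salt_frac, slice_thickness = slice_thickness,
                 unit = unit), class = "slice_profile")
}

#' Erf-profile inversion estimate of the effective diffusion coefficient
#'
#' Treating the one-way slab as semi-infinite with constant De, the depth
#' profile obeys
#' \deqn{\frac{C_s - C(x,t)}{C_s - C_0} = \mathrm{erf}\!\left(\frac{x}{2\sqrt{D_e t}}\right),}
#' so each slice with residual ratio r strictly inside (0, 1) yields
#' De_i = (x_i / (2 erfinv(r_i)))^2 / t. Saturated (r <= 0) or untouched
#' (r >= 1) slices carry no information and are excluded (and counted).
#'
#' @param profile a [slice_profile()].
#' @param cs boundary (brine) salt content, same units as the profile.
#' @param c0 initial tissue salt content.
#' @param aggregate `"mean"` (unweighted mean of slice-level De, default) or
#'   `"lsq"` (least squares of erfinv(r) on x, De from the fitted slope).
#' @return a [de_estimate()] with `method = "erf_profile"`.
#' @export
erf_profile_method <- function(profile, cs, c0 = 0,
                               aggregate = c("mean", "lsq")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(profile, "slice_profile"))
  if (cs <= c0) stop_brinesim("requires cs > c0 (salt uptake)", "invalid_profile")
  t_sec <- profile$time * 3600
  if (t_sec <= 0) stop_brinesim("profile time must be positive", "invalid_profile")
  x <- profile$slice_centers
  r <- (cs - profile$salt_frac) / (cs - c0)
  usable <- r > 0 & r < 1 & x > 0
  n_excl <- sum(!usable)
  if (!any(usable))
    stop_brinesim("no usable slices: all saturated, untouched, or at depth 0",
                  "estimation_failure")
  xi <- x[usable]; ri <- r[usable]
  ei <- pracma::erfinv(ri)
  if (aggregate == "mean") {
    de_i <- (xi / (2 * ei))^2 / t_sec
    de_hat <- mean(de_i)
    r2 <- NA_real_
  } else {
    fit <- stats::lm(ei ~ xi - 1)   # erfinv(r) = x / (2 sqrt(De t))
    slope <- unname(coef(fit))[1]
    de_hat <- 1 / (4 * slope^2 * t_sec)
    r2 <- r_squared(ei, stats::fitted(fit))
  }
  de_estimate(de = de_hat, r2 = r2, method = "erf_profile",
              n_points = sum(usable), excluded = n_excl)
}

#' Effective diffusivity implied by a fitted time-variant model
#'
#' Evaluates the fitted aqueous-salt trajectory Z(t) on a time grid, forms
#' the driving-force complement 1 - Y(t) against the equilibrium state
#' (with the brine held at y_t = z_e), and applies the slope method. This
#' reconstructs a De from a smooth model of the composition data rather
#' than from the raw points.
#'
#' @param fit a `"time_variant_fit"`.
#' @param eq an [equilibrium_state()].
#' @param thickness_L slab thickness, metres.
#' @param grid evaluation times, hours.
#' @return a [de_estimate()] with `method = "from_time_model"`.
#' @export
de_from_time_model <- function(fit, eq, thickness_L = 0.01,
                               grid = seq(2, 24, by = 2)) {
  stopifnot(inherits(fit, "time_variant_fit"), inherits(eq, "equilibrium_state"))
  z <- predict(fit, grid)
  omy <- driving_force_complement(z, yt = eq$ze, z0 = eq$z0, ze = eq$ze)
  est <- slope_method(grid, omy, thickness_L, time_unit = "hours")
  est$method <- "from_time_model"
  est
}

#' Sliding-window diffusivity estimates
#'
#' Applies the slope method to consecutive windows of the driving-force
#' series, tracing how the apparent De evolves over curing (matrix
#' structural changes make it drift downward in practice).
#'
#' @param times hours.
#' @param one_minus_Y driving-force complements.
#' @param thickness_L slab thickness, metres.
#' @param window window length in timepoints (>= 3).
#' @return a list of [de_estimate()]s, one per window position; the window
#'   start times are in attribute `"window_start"`.
#' @export
windowed_de <- function(times, one_minus_Y, thickness_L, window = 4L) {
  if (window < 3) stop_brinesim("window must span at least 3 points", "insufficient_data")
  n <- length(times)
  if (n < window) stop_brinesim("series shorter than window", "insufficient_data")
  starts <- seq_len(n - window + 1)
  out <- lapply(starts, function(i) {
    idx <- i:(i + window - 1)
    slope_method(times[idx], one_minus_Y[idx], thickness_L)
  })
  attr(out, "window_start") <- times[starts]
  out
}
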