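#' Percent change in total sample weight
#'
#' @param mt sample mass at time t (g).
#' @param m0 initial sample mass (g).
#' @return signed percent change, 100 (mt - m0) / m0.
#' @export
weight_change <- function(mt, m0) {
  if (any(m0 <= 0)) stop_brinesim("initial mass must be positive", "invalid_mass")
  100 * (mt - m0) / m0
}

#' Percent change in a component (moisture or salt) mass
#'
#' The change is referenced to the initial total mass, so moisture and salt
#' changes are directly comparable with the total weight change.
#'
#' @param mt sample mass at time t (g).
#' @param xt component mass fraction at time t.
#' @param m0 initial sample mass (g).
#' @param x0 initial component mass fraction.
#' @return signed percent change, 100 (mt xt - m0 x0) / m0.
#' @export
component_change <- function(mt, xt, m0, x0) {
  if (any(m0 <= 0)) stop_brinesim("initial mass must be positive", "invalid_mass")
  100 * (mt * xt - m0 * x0) / m0
}

#' Build a change series
#'
#' A change series is the trajectory of one percent-change variable (total
#' weight, moisture, or salt) over the curing schedule.
#'
#' @param variable one of `"total"`, `"water"`, `"salt"`.
#' @param times curing times in hours, strictly increasing.
#' @param delta_percent signed percent changes; must be 0 wherever time is 0.
#' @return an object of class `"change_series"`.
#' @export
change_series <- function(variable = c("total", "water", "salt"),
                          times, delta_percent) {
  variable <- match.arg(variable)
  stopifnot(length(times) == length(delta_percent))
  if (any(diff(times) <= 0))
    stop_brinesim("times must be strictly increasing", "invalid_series")
  if (any(times == 0 & abs(delta_percent) > 1e-12))
    stop_brinesim("change at t = 0 must be 0", "invalid_series")
  structure(list(variable = variable, times = times,
                 delta_percent = delta_percent), class = "change_series")
}

#' Square-root-of-time mass-transfer kinetic fit
#'
#' Fits the diffusion-controlled kinetic law in relative-mass form,
#' \deqn{y(t) = 1 + \Delta M(t)/100 = k_1 + k_2 \sqrt{t},}
#' by ordinary least squares of y on sqrt(t) (t in hours). The intercept
#' k1 captures the fast initial stage (surface uptake, pressure-driven
#' exchange); the slope k2 (h^-0.5) is the diffusion-controlled
#' mass-transfer rate and is the parameter that additives such as xylitol
#' modulate.
#'
#' @param series a [change_series()], or anything coercible via a list with
#'   `times` (hours) and `delta_percent` fields.
#' @return an object of class `"sqrt_kinetic_fit"` with fields `k1`, `k2`,
#'   `r2`, `variable`, `n`.
#' @examples
#' s <- change_series("salt", times = seq(2, 24, by = 2),
#'                    delta_percent = 100 * (0.99072 + 0.010715 *
#'                                           sqrt(seq(2, 24, by = 2)) - 1))
#' fit_sqrt_kinetics(s)
#' @export
fit_sqrt_kinetics <- function(series) {
  times <- series$times
  dm <- series$delta_percent
  if (length(unique(times)) < 3)
    stop_brinesim("need at least 3 distinct timepoints", "insufficient_data")
  y <- 1 + dm / 100
  fit <- stats::lm(y ~ I(sqrt(times)))
  k <- unname(coef(fit))
  r2 <- r_squared(y, stats::fitted(fit))
  structure(list(k1 = k[1], k2 = k[2], r2 = r2,
                 variable = series$variable %||% NA_character_,
                 n = length(times)),
            class = "sqrt_kinetic_fit")
}

#' Evaluate the square-root kinetic law
#'
#' @param k1,k2 intercept (dimensionless) and slope (h^-0.5).
#' @param times hours.
#' @return the relative mass y(t) = k1 + k2 sqrt(t).
#' @export
kinetic_line <- function(k1, k2, times) k1 + k2 * sqrt(times)

#' @export
print.sqrt_kinetic_fit <- function(x, ...) {
  cat(sprintf("sqrt-time kinetic fit (%s): k1 = %.6g, k2 = %.6g h^-0.5, R2 = %.4f (n = %d)\n",
              x$variable, x$k1, x$k2, x$r2, x$n))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# R^2 = 1 - RSS/TSS, with the convention that an exact fit of a constant
# response scores 1
r_squared <- function(y, yhat) {
  tss <- sum((y - mean(y))^2)
  rss <- sum((y - yhat)^2)
  if (tss == 0) return(if (rss < 1e-28) 1 else 0)
  max(0, min(1, 1 - rss / tss))
}
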