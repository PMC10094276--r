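#' Time-variant models for aqueous-phase NaCl content
#'
#' Fits one of three empirical models for the tissue's aqueous-phase salt
#' content Z(t) over curing time t (hours):
#' \describe{
#'   \item{linear}{Z = A t + b}
#'   \item{power}{Z = A t^b + c, b > 0}
#'   \item{exponential}{Z = A (1 - e^(-b t)), A > 0, b > 0 (saturation to A)}
#' }
#' The nonlinear forms are fitted by profiled least squares: for a trial
#' exponent/rate b the remaining parameters are linear and solved exactly,
#' so the optimisation reduces to one dimension in b. A log-spaced
#' multi-start grid brackets the optimum, `optimize()` refines it, and a
#' Levenberg-Marquardt polish ([minpack.lm::nlsLM()]) brings all parameters
#' to machine precision. Convergence tolerance is 1e-10 on relative
#' parameter change.
#'
#' @param form one of `"linear"`, `"power"`, `"exponential"`.
#' @param times curing times in hours.
#' @param z aqueous-phase salt fractions in \[0, 1\].
#' @param b_range multi-start search range for the exponent/rate b (h^-1
#'   for the exponential form, dimensionless for the power form).
#' @return an object of class `"time_variant_fit"`: `form`, `A`, `b`, `c`
#'   (0 for forms without it), `r2`, `rss`, `n`.
#' @examples
#' t <- seq(2, 24, by = 2)
#' z <- 0.026587 * t^0.212376 + 0.005467
#' fit_time_model("power", t, z)
#' @export
fit_time_model <- function(form = c("linear", "power", "exponential"),
                           times, z, b_range = c(1e-3, 5)) {
  form <- match.arg(form)
  stopifnot(length(times) == length(z))
  if (any(z < 0 | z > 1))
    stop_brinesim("z must be a fraction in [0, 1]", "invalid_series")
  npar <- c(linear = 2L, power = 3L, exponential = 2L)[[form]]
  if (length(unique(times)) < npar)
    stop_brinesim("need at least as many distinct timepoints as parameters",
                  "insufficient_data")
  out <- switch(form,
    linear = {
      fit <- stats::lm(z ~ times)
      cf <- unname(coef(fit))
      list(A = cf[2], b = cf[1], c = 0, rss = sum(stats::resid(fit)^2))
    },
    power = fit_profiled(times, z, b_range,
                         basis = function(b, t) t^b, with_offset = TRUE),
    exponential = fit_profiled(times, z, b_range,
                               basis = function(b, t) 1 - exp(-b * t),
                               with_offset = FALSE)
  )
  if (!all(is.finite(c(out$A, out$b, out$c, out$rss))))
    stop_brinesim(sprintf("%s fit failed to converge (A=%g, b=%g, rss=%g)",
                          form, out$A, out$b, out$rss), "fit_failure")
  tss <- sum((z - mean(z))^2)
  r2 <- if (tss > 0) 1 - out$rss / tss else 1
  structure(list(form = form, A = out$A, b = out$b, c = out$c,
                 r2 = max(0, min(1, r2)), rss = out$rss, n = length(times)),
            class = "time_variant_fit")
}

# profiled 1D least squares over the nonlinear parameter b:
# z ~ A * basis(b, t) [+ c]; A (and c) solved by linear LS at each b,
# b located on a log grid then refined, final LM polish.
fit_profiled <- function(times, z, b_range, basis, with_offset) {
  rss_at <- function(b) {
    g <- basis(b, times)
    if (any(!is.finite(g))) return(Inf)
    fit <- if (with_offset) stats::lm(z ~ g) else stats::lm(z ~ g - 1)
    sum(stats::resid(fit)^2)
  }
  grid <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = 60))
  rss <- vapply(grid, rss_at, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-12)
  b <- opt$minimum
  g <- basis(b, times)
  fit <- if (with_offset) stats::lm(z ~ g) else stats::lm(z ~ g - 1)
  cf <- unname(coef(fit))
  if (with_offset) { A <- cf[2]; cc <- cf[1] } else { A <- cf[1]; cc <- 0 }
  # LM polish of all parameters jointly
  polished <- tryCatch({
    df <- data.frame(t = times, z = z)
    if (with_offset) {
      nfit <- minpack.lm::nlsLM(z ~ A * t^b + c, data = df,
                                start = list(A = A, b = b, c = cc),
                                lower = c(-Inf, 1e-8, -Inf),
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    } else {
      nfit <- minpack.lm::nlsLM(z ~ A * (1 - exp(-b * t)), data = df,
                                start = list(A = A, b = b),
                                lower = c(1e-12, 1e-8),
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    }
    p <- as.list(coef(nfit))
    list(A = p$A, b = p$b, c = p$c %||% 0,
         rss = sum(stats::resid(nfit)^2))
  }, error = function(e) NULL)
  base <- list(A = A, b = b, c = cc, rss = sum(stats::resid(fit)^2))
  if (!is.null(polished) && polished$rss <= base$rss + 1e-300) polished else base
}

#' Joint power-model fit with a shared exponent
#'
#' Fits Z = A_g t^b + c_g across several groups with one common exponent b,
#' minimising the pooled residual sum of squares. For a given b the
#' per-group (A, c) are linear and solved exactly, so the shared exponent
#' is found by one-dimensional profiled optimisation.
#'
#' @param groups a list; each element a list with `times` and `z`.
#' @param b_range search range for the shared exponent.
#' @return a list of `"time_variant_fit"` objects (one per group, same `b`),
#'   with attribute `"shared_b"`.
#' @export
fit_power_joint <- function(groups, b_range = c(1e-3, 5)) {
  if (length(groups) < 2)
    stop_brinesim("joint fit needs at least 2 groups", "insufficient_data")
  pooled_rss <- function(b) {
    sum(vapply(groups, function(g) {
      gg <- g$times^b
      sum(stats::resid(stats::lm(g$z ~ gg))^2)
    }, numeric(1)))
  }
  grid <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = 60))
  rss <- vapply(grid, pooled_rss, numeric(1))
  i <- which.min(rss)
  opt <- stats::optimize(pooled_rss,
                         c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                         tol = 1e-12)
  b <- opt$minimum
  fits <- lapply(groups, function(g) {
    gg <- g$times^b
    fit <- stats::lm(g$z ~ gg)
    cf <- unname(coef(fit))
    rssg <- sum(stats::resid(fit)^2)
    tss <- sum((g$z - mean(g$z))^2)
    structure(list(form = "power", A = cf[2], b = b, c = cf[1],
                   r2 = if (tss > 0) max(0, min(1, 1 - rssg / tss)) else 1,
                   rss = rssg, n = length(g$times)),
              class = "time_variant_fit")
  })
  attr(fits, "shared_b") <- b
  fits
}

#' Predict from a time-variant fit
#'
#' @param object a `"time_variant_fit"`.
#' @param t times in hours (>= 0).
#' @param ... unused.
#' @return model values at `t`.
#' @export
predict.time_variant_fit <- function(object, t, ...) {
  stopifnot(all(t >= 0))
  switch(object$form,
         linear = object$A * t + object$b,
         power = object$A * t^object$b + object$c,
         exponential = object$A * (1 - exp(-object$b * t)))
}

#' Rank fitted models by goodness of fit
#'
#' Orders fits by decreasing R^2; ties are broken in favour of the model
#' with fewer parameters.
#'
#' @param fits a list of `"time_variant_fit"` objects.
#' @return the same list, reordered.
#' @export
rank_models <- function(fits) {
  if (length(fits) == 0) stop_brinesim("no fits to rank", "insufficient_data")
  np <- vapply(fits, function(f)
    c(linear = 2L, power = 3L, exponential = 2L)[[f$form]], integer(1))
  r2 <- vapply(fits, function(f) f$r2, numeric(1))
  fits[order(-r2, np)]
}

#' @export
print.time_variant_fit <- function(x, ...) {
  eqn <- switch(x$form,
                linear = sprintf("Z = %.6g t + %.6g", x$A, x$b),
                power = sprintf("Z = %.6g t^%.6g + %.6g", x$A, x$b, x$c),
                exponential = sprintf("Z = %.6g (1 - exp(-%.6g t))", x$A, x$b))
  cat(sprintf("%s time-variant fit: %s, R2 = %.5f (n = %d)\n",
              x$form, eqn, x$r2, x$n))
  invisible(x)
}
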