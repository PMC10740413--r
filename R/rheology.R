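#' Power-law (Ostwald-de Waele) rheology parameters
#'
#' The pair (n, K) defining a shear-thinning viscosity curve
#' \eqn{\eta = K \dot\gamma^{n-1}}: `n` is the dimensionless power-law index
#' (shear-thinning when n < 1) and `K` the consistency coefficient in
#' Pa.s^n, numerically the apparent viscosity at unit shear rate.
#'
#' @param n Power-law index (> 0), dimensionless.
#' @param K Consistency coefficient (> 0), Pa.s^n.
#' @return An object of class `power_law_params`.
#' @examples
#' power_law_params(n = 0.54, K = 93.05)
#' @export
power_law_params <- function(n, K) {
  stopifnot(length(n) == 1L, length(K) == 1L)
  if (!is.finite(n) || n <= 0) stop("power-law index n must be finite and > 0")
  if (!is.finite(K) || K <= 0) stop("consistency coefficient K must be finite and > 0")
  structure(list(n = as.numeric(n), K = as.numeric(K)),
            class = "power_law_params")
}

#' @export
print.power_law_params <- function(x, ...) {
  cat(sprintf("Power-law fluid: n = %.4g, K = %.4g Pa.s^n%s\n",
              x$n, x$K, if (x$n < 1) " (shear-thinning)" else ""))
  invisible(x)
}

#' A measured shear-rate/viscosity flow curve
#'
#' Rotational-rheometry measurements of apparent viscosity over a sweep of
#' shear rates. Shear rates must be strictly increasing and all values finite
#' and positive. Temperature is carried as an annotation only.
#'
#' @param shear_rates Shear rates, 1/s, strictly increasing, length >= 2.
#' @param viscosities Apparent viscosities, Pa.s, same length.
#' @param temperature Measurement temperature, degrees C (annotation only).
#' @return An object of class `shear_viscosity_curve`.
#' @export
shear_viscosity_curve <- function(shear_rates, viscosities,
                                  temperature = NA_real_) {
  shear_rates <- as.numeric(shear_rates)
  viscosities <- as.numeric(viscosities)
  if (length(shear_rates) != length(viscosities))
    stop("shear_rates and viscosities must have equal length")
  if (length(shear_rates) < 2L)
    stop("insufficient data: a viscosity curve needs at least 2 points")
  if (!all(is.finite(shear_rates)) || !all(is.finite(viscosities)))
    stop("all shear rates and viscosities must be finite")
  if (any(shear_rates <= 0) || any(viscosities <= 0))
    stop("all shear rates and viscosities must be > 0")
  if (any(diff(shear_rates) <= 0))
    stop("shear rates must be strictly increasing")
  structure(list(shear_rates = shear_rates, viscosities = viscosities,
                 temperature = temperature),
            class = "shear_viscosity_curve")
}

#' @export
print.shear_viscosity_curve <- function(x, ...) {
  cat(sprintf(
    "Shear-viscosity curve: %d points, shear rate %.3g-%.3g 1/s%s\n",
    length(x$shear_rates), min(x$shear_rates), max(x$shear_rates),
    if (is.finite(x$temperature)) sprintf(", T = %g degC", x$temperature) else ""))
  invisible(x)
}

#' Apparent viscosity of a power-law fluid
#'
#' Evaluates \eqn{\eta = K \dot\gamma^{n-1}}. At unit shear rate the
#' viscosity equals K for any n; for n < 1 the curve is strictly decreasing
#' in shear rate.
#'
#' @param params A [power_law_params()] object.
#' @param shear_rate Shear rate(s), 1/s, all > 0. Vectorized.
#' @return Apparent viscosity, Pa.s.
#' @examples
#' power_law_viscosity(power_law_params(0.5, 55), 100) # 5.5
#' @export
power_law_viscosity <- function(params, shear_rate) {
  stopifnot(inherits(params, "power_law_params"))
  if (any(!is.finite(shear_rate)) || any(shear_rate <= 0))
    stop("shear_rate must be finite and > 0")
  params$K * shear_rate^(params$n - 1)
}

#' Fit the power-law model to a viscosity curve
#'
#' Ordinary least squares of log(viscosity) on log(shear rate): the slope is
#' n - 1 and the intercept log K. Fitting in log-log space is the standard
#' choice for flow curves spanning decades of shear rate and recovers
#' noise-free power-law data exactly.
#'
#' @param curve A [shear_viscosity_curve()].
#' @return A list of class `power_law_fit`: `params` ([power_law_params()]),
#'   `r_squared` (coefficient of determination in log-log space) and
#'   `residuals_log` (log-space residuals).
#' @export
fit_power_law <- function(curve) {
  stopifnot(inherits(curve, "shear_viscosity_curve"))
  lg <- log(curve$shear_rates)
  le <- log(curve$viscosities)
  if (stats::var(lg) <= 0)
    stop("degenerate design: zero variance in log shear rate")
  fit <- stats::lm(le ~ lg)
  beta <- stats::coef(fit)
  sst <- sum((le - mean(le))^2)
  ssr <- sum(stats::residuals(fit)^2)
  r2 <- if (sst > 0) 1 - ssr / sst else as.numeric(ssr < 1e-20)
  structure(list(
    params = power_law_params(n = unname(beta[2]) + 1, K = exp(unname(beta[1]))),
    r_squared = r2,
    residuals_log = unname(stats::residuals(fit))
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: n = %.4f, K = %.4f Pa.s^n (log-log R^2 = %.4f)\n",
              x$params$n, x$params$K, x$r_squared))
  invisible(x)
}

#' Read / write viscosity-curve CSV files
#'
#' Columns `shear_rate_per_s, viscosity_pa_s`, header required, UTF-8,
#' '.' decimal separator.
#'
#' @param path File path.
#' @return [read_viscosity_curve()] returns a [shear_viscosity_curve()].
#' @export
read_viscosity_curve <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("shear_rate_per_s", "viscosity_pa_s")
  if (!all(need %in% names(df)))
    stop("viscosity CSV must have columns: ", paste(need, collapse = ", "))
  shear_viscosity_curve(df$shear_rate_per_s, df$viscosity_pa_s)
}

#' @param curve A [shear_viscosity_curve()] to write.
#' @rdname read_viscosity_curve
#' @export
write_viscosity_curve <- function(curve, path) {
  stopifnot(inherits(curve, "shear_viscosity_curve"))
  utils::write.csv(
    data.frame(shear_rate_per_s = curve$shear_rates,
               viscosity_pa_s = curve$viscosities),
    path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
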