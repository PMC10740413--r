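#' Axisymmetric nozzle geometry
#'
#' A piecewise channel of cylindrical (equal radii) and conical (linear taper)
#' segments, described in mm. Radii must be continuous across segment joints;
#' the final outlet radius is the tip inner radius.
#'
#' @param segments Data frame with columns `length_mm`, `r_in_mm`, `r_out_mm`
#'   (one row per axial segment, in flow order).
#' @return An object of class `nozzle_geometry`.
#' @export
nozzle_geometry <- function(segments) {
  segments <- as.data.frame(segments)
  need <- c("length_mm", "r_in_mm", "r_out_mm")
  if (!all(need %in% names(segments)))
    stop("segments must have columns: ", paste(need, collapse = ", "))
  segments <- segments[need]
  m <- as.matrix(segments)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all segment lengths and radii must be finite and > 0")
  if (nrow(segments) > 1 &&
      any(abs(segments$r_out_mm[-nrow(segments)] - segments$r_in_mm[-1]) >
          1e-12))
    stop("radii must be continuous across segment joints")
  segments$type <- ifelse(abs(segments$r_in_mm - segments$r_out_mm) < 1e-12,
                          "cylindrical", "conical")
  structure(list(segments = segments), class = "nozzle_geometry")
}

#' Default syringe-plus-needle geometry
#'
#' A 3 mL syringe barrel feeding a 25 G needle tip (0.25 mm inner diameter):
#' barrel R 4.8 mm x L 10 mm, conical hub taper 4.8 to 0.125 mm over 20 mm,
#' cylindrical needle lumen R 0.125 mm x L 25 mm (the standard 25 G length).
#' Measured dimensions of the simulated channel are not available, so this
#' footprint is a calibrated assumption: it is the plain reading of the
#' stated hardware and puts the solver's flow-rate scale over the printable
#' (n, K, P) box in the low single-digit uL/s range reported for that space.
#' Fully configurable.
#'
#' @return A [nozzle_geometry()].
#' @export
default_nozzle_geometry <- function() {
  nozzle_geometry(data.frame(
    length_mm = c(10, 20, 25),
    r_in_mm = c(4.8, 4.8, 0.125),
    r_out_mm = c(4.8, 0.125, 0.125)
  ))
}

#' @export
print.nozzle_geometry <- function(x, ...) {
  s <- x$segments
  cat(sprintf("Nozzle geometry: %d segments, total length %.3g mm, exit radius %.3g mm\n",
              nrow(s), sum(s$length_mm), s$r_out_mm[nrow(s)]))
  print(s)
  invisible(x)
}

# unit conversions at interfaces: mm / kPa / uL/s outside, SI inside
UL_S <- 1e-9   # m^3/s per uL/s
MM <- 1e-3     # m per mm
KPA <- 1e3     # Pa per kPa

#' Fully developed pressure gradient of power-law tube flow
#'
#' The generalized Hagen-Poiseuille closure for a power-law fluid in a
#' circular tube: \eqn{dP/dz = (2K/R) ((3n+1)/n \cdot Q/(\pi R^3))^n}.
#' For n = 1 it reduces to the Newtonian gradient \eqn{8\mu Q/(\pi R^4)}.
#'
#' @param params A [power_law_params()].
#' @param Q Flow rate, uL/s (> 0).
#' @param R Local tube radius, mm (> 0). Vectorized over `R`.
#' @return Pressure gradient magnitude, Pa/m.
#' @export
local_pressure_gradient <- function(params, Q, R) {
  stopifnot(inherits(params, "power_law_params"))
  if (!is.finite(Q) || Q <= 0) stop("Q must be finite and > 0")
  if (any(!is.finite(R)) || any(R <= 0)) stop("R must be finite and > 0")
  q <- Q * UL_S
  r <- R * MM
  (2 * params$K / r) * ((3 * params$n + 1) / params$n * q / (pi * r^3))^params$n
}

# SI-core gradient used in quadrature loops (q m^3/s, r m) -> Pa/m
gradient_si <- function(n, K, q, r) {
  (2 * K / r) * ((3 * n + 1) / n * q / (pi * r^3))^n
}

#' Pressure drop through a nozzle at a given flow rate
#'
#' Integrates the locally fully developed (lubrication-approximation) pressure
#' gradient along the channel axis: cylindrical segments use the closed-form
#' gradient times length; conical segments are integrated along the linear
#' taper by composite Simpson quadrature with a fixed panel count.
#'
#' @inheritParams local_pressure_gradient
#' @param geometry A [nozzle_geometry()].
#' @param n_panels Simpson panels per conical segment (even; default 2048).
#' @param profile If `TRUE`, also return the axial pressure profile.
#' @return If `profile = FALSE`, the total pressure drop in kPa; otherwise a
#'   list with `delta_p_kpa` and `profile` (data frame `z_mm`, `p_kpa`, with
#'   P decreasing from the applied value at the inlet to 0 at the outlet).
#' @export
pressure_drop <- function(params, geometry, Q, n_panels = 2048L,
                          profile = FALSE) {
  stopifnot(inherits(params, "power_law_params"),
            inherits(geometry, "nozzle_geometry"))
  if (!is.finite(Q) || Q <= 0) stop("Q must be finite and > 0")
  if (n_panels %% 2L != 0L) n_panels <- n_panels + 1L
  n <- params$n; K <- params$K
  q <- Q * UL_S
  segs <- geometry$segments
  drops <- numeric(nrow(segs))        # Pa
  prof_z <- 0; prof_cum <- 0          # cumulative drop at axial stations
  z0 <- 0
  for (i in seq_len(nrow(segs))) {
    L <- segs$length_mm[i] * MM
    r0 <- segs$r_in_mm[i] * MM
    r1 <- segs$r_out_mm[i] * MM
    if (segs$type[i] == "cylindrical") {
      drops[i] <- gradient_si(n, K, q, r0) * L
      if (profile) {
        prof_z <- c(prof_z, z0 + L)
        prof_cum <- c(prof_cum, prof_cum[length(prof_cum)] + drops[i])
      }
    } else {
      z <- seq(0, L, length.out = n_panels + 1L)
      g <- gradient_si(n, K, q, r0 + (r1 - r0) * z / L)
      h <- L / n_panels
      # composite Simpson over successive panel pairs (cumulative at even nodes)
      even <- seq(1L, n_panels + 1L, by = 2L)             # 1-based odd indices
      blocks <- (h / 3) * (g[even[-length(even)]] +
                             4 * g[even[-length(even)] + 1L] +
                             g[even[-1]])
      drops[i] <- sum(blocks)
      if (profile) {
        prof_z <- c(prof_z, z0 + z[even[-1]])
        prof_cum <- c(prof_cum, prof_cum[length(prof_cum)] + cumsum(blocks))
      }
    }
    z0 <- z0 + L
  }
  total <- sum(drops) / KPA
  if (!profile) return(total)
  list(delta_p_kpa = total,
       profile = data.frame(z_mm = prof_z / MM,
                            p_kpa = (sum(drops) - prof_cum) / KPA))
}

# exit velocity profile of fully developed power-law tube flow (SI), m/s
exit_velocity_si <- function(n, K, G, R, r) {
  (G / (2 * K))^(1 / n) * n / (n + 1) * (R^(1 + 1 / n) - r^(1 + 1 / n))
}

#' Solve the flow rate through a nozzle at a given driving pressure
#'
#' Inverts [pressure_drop()] by bracketed root finding on log Q (the drop is
#' strictly increasing in Q). Returns the full solution: flow rate, axial
#' pressure profile, exit velocity profile and exit wall shear rate.
#'
#' @inheritParams pressure_drop
#' @param pressure Applied pressure drop, kPa (> 0).
#' @param n_radial Radial grid points for the exit velocity profile.
#' @return An object of class `flow_solution` with fields `Q_ul_s`,
#'   `delta_p_kpa`, `pressure_profile` (`z_mm`, `p_kpa`), `exit_profile`
#'   (`r_mm`, `u_mm_s`), `wall_shear_rate_per_s`, `params`, `geometry`.
#' @export
solve_flow_rate <- function(params, geometry, pressure, n_panels = 2048L,
                            n_radial = 513L) {
  stopifnot(inherits(params, "power_law_params"),
            inherits(geometry, "nozzle_geometry"))
  if (!is.finite(pressure) || pressure <= 0)
    stop("pressure must be finite and > 0")
  f <- function(logQ)
    log(pressure_drop(params, geometry, exp(logQ), n_panels)) - log(pressure)
  lo <- log(1e-6); hi <- log(1e3)
  it <- 0L
  while (f(lo) > 0 && it < 60L) { lo <- lo - log(2); it <- it + 1L }
  while (f(hi) < 0 && it < 60L) { hi <- hi + log(2); it <- it + 1L }
  if (f(lo) > 0 || f(hi) < 0)
    stop("flow-rate bracket failure after expansion cap: pressure = ",
         pressure, " kPa, n = ", params$n, ", K = ", params$K)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  Q <- exp(root$root)

  pd <- pressure_drop(params, geometry, Q, n_panels, profile = TRUE)
  segs <- geometry$segments
  R_exit <- segs$r_out_mm[nrow(segs)] * MM
  G <- gradient_si(params$n, params$K, Q * UL_S, R_exit)
  r <- seq(0, R_exit, length.out = n_radial)
  u <- exit_velocity_si(params$n, params$K, G, R_exit, r)
  wall_sr <- (3 * params$n + 1) / params$n * (Q * UL_S) / (pi * R_exit^3)

  structure(list(
    Q_ul_s = Q,
    delta_p_kpa = pressure,
    pressure_profile = pd$profile,
    exit_profile = data.frame(r_mm = r / MM, u_mm_s = u / MM),
    wall_shear_rate_per_s = wall_sr,
    params = params,
    geometry = geometry
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "Flow solution: Q = %.4g uL/s at %.4g kPa (n = %.3g, K = %.3g Pa.s^n)\n",
    x$Q_ul_s, x$delta_p_kpa, x$params$n, x$params$K))
  cat(sprintf("  exit wall shear rate %.4g 1/s, centerline velocity %.4g mm/s\n",
              x$wall_shear_rate_per_s, max(x$exit_profile$u_mm_s)))
  invisible(x)
}

#' Flow rate by radial integration of a velocity profile
#'
#' Computes \eqn{Q = 2\pi \int_0^R u(r) r\, dr} by composite quadrature
#' (Simpson on uniform odd-length grids, trapezoid otherwise). The no-slip
#' condition u(R) = 0 is checked against the profile's own scale.
#'
#' @param r Radial grid, mm, increasing from 0 to the tube radius.
#' @param u Axial velocity at `r`, mm/s.
#' @return Flow rate, uL/s.
#' @export
flow_rate_from_profile <- function(r, u) {
  if (length(r) != length(u) || length(r) < 3L)
    stop("r and u must have equal length >= 3")
  if (any(diff(r) <= 0)) stop("r must be strictly increasing")
  umax <- max(abs(u))
  if (umax > 0 && abs(u[length(u)]) > 1e-6 * umax)
    warning("u at the wall is not ~0; integrating a slipping profile")
  g <- u * r                               # integrand in mm^2/s * mm
  h <- diff(r)
  uniform <- max(abs(h - h[1])) < 1e-9 * h[1]
  npts <- length(r)
  if (uniform && npts %% 2L == 1L) {
    w <- rep(c(4, 2), length.out = npts - 2L)
    integral <- h[1] / 3 * (g[1] + sum(w * g[2:(npts - 1L)]) + g[npts])
  } else {
    integral <- sum((g[-1] + g[-npts]) / 2 * h)
  }
  2 * pi * integral                        # mm^3/s == uL/s
}

#' Deposited filament diameter from flow rate and print speed
#'
#' Volume conservation of an extruded stream stretched into a uniform
#' cylinder moving with the print head: \eqn{d = 2\sqrt{Q/(\pi v)}}.
#'
#' @param Q Flow rate, uL/s (> 0). Vectorized.
#' @param v Print speed, mm/s (> 0). Vectorized.
#' @return Filament diameter, mm.
#' @examples
#' filament_diameter(pi, 4) # 1 mm
#' @export
filament_diameter <- function(Q, v) {
  if (any(!is.finite(Q)) || any(Q <= 0)) stop("Q must be finite and > 0")
  if (any(!is.finite(v)) || any(v <= 0)) stop("v must be finite and > 0")
  2 * sqrt(Q / (pi * v))
}
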