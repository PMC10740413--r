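# independent oracles and shared fixtures, built in code

# endpoint-inclusive log-uniform shear-rate grid
log_grid <- function(lo = 1, hi = 100, n = 21) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# brute-force pressure drop through a linearly tapered cone by midpoint
# slicing (independent of the package's Simpson quadrature)
brute_cone_drop_kpa <- function(n, K, Q_ul_s, r0_mm, r1_mm, L_mm,
                                slices = 1e6) {
  q <- Q_ul_s * 1e-9
  L <- L_mm * 1e-3
  z <- (seq_len(slices) - 0.5) / slices * L
  r <- (r0_mm + (r1_mm - r0_mm) * z / L) * 1e-3
  g <- (2 * K / r) * ((3 * n + 1) / n * q / (pi * r^3))^n
  sum(g) * (L / slices) / 1e3
}

# closed-form power-law flow rate through a single cylinder (uL/s)
cylinder_Q_closed <- function(n, K, R_mm, L_mm, dp_kpa) {
  R <- R_mm * 1e-3
  G <- dp_kpa * 1e3 / (L_mm * 1e-3)
  (G * R / (2 * K))^(1 / n) * pi * R^3 * n / (3 * n + 1) / 1e-9
}

# published validation compositions with their tabulated predictions and
# measurements (n and K in Pa.s) and printed accuracy percentages
validation_table <- function() {
  data.frame(
    Gel = c(10, 6, 7, 7.5, 9), SA = c(4, 5, 4, 3, 5), MC = c(3, 4, 4, 2, 3),
    n_pred = c(0.45, 0.55, 0.59, 0.67, 0.46),
    n_meas = c(0.44, 0.55, 0.58, 0.65, 0.46),
    n_acc_pct = c(97.06, 99.47, 98.59, 96.85, 99.32),
    K_pred = c(161.44, 81.57, 62.85, 12.80, 184.07),
    K_meas = c(146.02, 80.98, 60.52, 15.41, 147.79),
    K_acc_pct = c(90.44, 99.28, 96.30, 79.62, 80.29)
  )
}

# published model coefficients (uncoded wt% units) for recovery tests
eq_n_coefs <- c(
  "(Intercept)" = -0.256, "Gel" = 0.1638, "SA" = 0.1596, "MC" = 0.1828,
  "Gel^2" = -0.01107, "SA^2" = -0.0259, "MC^2" = -0.0213, "Gel:MC" = -0.01348
)

# small fast geometry for solver-heavy tests
small_geometry <- function() {
  nozzle_geometry(data.frame(length_mm = c(5, 10, 5),
                             r_in_mm = c(2, 2, 0.125),
                             r_out_mm = c(2, 0.125, 0.125)))
}
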