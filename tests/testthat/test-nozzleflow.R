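test_that("local pressure gradient matches closed forms", {
  # Newtonian limit: 8 mu Q / (pi R^4)
  mu <- 0.7; Q <- 2; R <- 0.3
  expect_equal(local_pressure_gradient(power_law_params(1, mu), Q, R),
               8 * mu * (Q * 1e-9) / (pi * (R * 1e-3)^4), tolerance = 1e-12)
  # linear in K
  g1 <- local_pressure_gradient(power_law_params(0.6, 20), 1, 0.2)
  g2 <- local_pressure_gradient(power_law_params(0.6, 40), 1, 0.2)
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
  # hand-evaluated shear-thinning case
  expect_equal(local_pressure_gradient(power_law_params(0.5, 55), 0.158, 0.125),
               9.985e6, tolerance = 1e-3)
  expect_error(local_pressure_gradient(power_law_params(0.5, 55), -1, 0.1),
               "Q")
})

test_that("geometry validation enforces continuity and positivity", {
  expect_error(nozzle_geometry(data.frame(length_mm = 1, r_in_mm = -1,
                                          r_out_mm = 1)), "> 0")
  expect_error(nozzle_geometry(data.frame(length_mm = c(1, 1),
                                          r_in_mm = c(1, 0.5),
                                          r_out_mm = c(0.8, 0.5))),
               "continuous")
  g <- default_nozzle_geometry()
  expect_equal(g$segments$type, c("cylindrical", "conical", "cylindrical"))
})

test_that("cylinder pressure drops match Hagen-Poiseuille and add in series", {
  cyl <- nozzle_geometry(data.frame(length_mm = 10, r_in_mm = 0.125,
                                    r_out_mm = 0.125))
  mu <- 1; Q <- 0.5
  hp <- 8 * mu * (10e-3) * (Q * 1e-9) / (pi * (0.125e-3)^4) / 1e3
  expect_equal(pressure_drop(power_law_params(1, mu), cyl, Q), hp,
               tolerance = 1e-6)
  two <- nozzle_geometry(data.frame(length_mm = c(6, 4),
                                    r_in_mm = c(0.125, 0.125),
                                    r_out_mm = c(0.125, 0.125)))
  expect_equal(pressure_drop(power_law_params(0.6, 30), two, Q),
               pressure_drop(power_law_params(0.6, 30),
                             nozzle_geometry(data.frame(length_mm = 6,
                                                        r_in_mm = 0.125,
                                                        r_out_mm = 0.125)), Q) +
                 pressure_drop(power_law_params(0.6, 30),
                               nozzle_geometry(data.frame(length_mm = 4,
                                                          r_in_mm = 0.125,
                                                          r_out_mm = 0.125)), Q),
               tolerance = 1e-10)
})

test_that("conical drops match the brute-force slice oracle", {
  cone <- nozzle_geometry(data.frame(length_mm = 20, r_in_mm = 1,
                                     r_out_mm = 0.125))
  got <- pressure_drop(power_law_params(0.575, 55), cone, 1)
  oracle <- brute_cone_drop_kpa(0.575, 55, 1, 1, 0.125, 20)
  expect_equal(got, oracle, tolerance = 1e-5)
  # second parameter set
  got2 <- pressure_drop(power_law_params(0.45, 10), cone, 0.2)
  expect_equal(got2, brute_cone_drop_kpa(0.45, 10, 0.2, 1, 0.125, 20),
               tolerance = 1e-5)
})

test_that("the axial pressure profile is monotone and lands on zero", {
  pd <- pressure_drop(power_law_params(0.575, 55), default_nozzle_geometry(),
                      0.5, profile = TRUE)
  p <- pd$profile$p_kpa
  expect_true(all(diff(p) <= 0))
  expect_equal(p[1], pd$delta_p_kpa, tolerance = 1e-12)
  expect_equal(p[length(p)], 0, tolerance = 1e-12)
})

test_that("flow-rate solves invert the pressure drop", {
  cyl <- nozzle_geometry(data.frame(length_mm = 10, r_in_mm = 0.125,
                                    r_out_mm = 0.125))
  sol <- solve_flow_rate(power_law_params(1, 1), cyl, 100)
  expect_equal(sol$Q_ul_s, pi * (0.125e-3)^4 * 1e5 / (8 * 1 * 0.01) / 1e-9,
               tolerance = 1e-8)
  # closed-form power-law cylinder
  expect_equal(solve_flow_rate(power_law_params(0.5, 30), cyl, 200)$Q_ul_s,
               cylinder_Q_closed(0.5, 30, 0.125, 10, 200), tolerance = 1e-8)
  # inverse consistency over random parameters on a mixed geometry
  set.seed(12)
  for (i in 1:50) {
    p <- power_law_params(runif(1, 0.4, 1.1), runif(1, 5, 150))
    Q0 <- 10^runif(1, -2, 1)
    dp <- pressure_drop(p, small_geometry(), Q0)
    expect_equal(solve_flow_rate(p, small_geometry(), dp)$Q_ul_s, Q0,
                 tolerance = 1e-8)
  }
  expect_error(solve_flow_rate(power_law_params(1, 1), cyl, -5), "pressure")
})

test_that("default-geometry flow at reference conditions sits in the reported envelope", {
  # order-of-magnitude envelope: reported flow rates for the sampled space
  # lie in 0-4 uL/s
  q <- solve_flow_rate(power_law_params(0.575, 55),
                       default_nozzle_geometry(), 250)$Q_ul_s
  expect_gt(q, 0)
  expect_lt(q, 4)
})

test_that("profile integration recovers the flow rate", {
  # plug flow
  r <- seq(0, 0.2, length.out = 513)
  expect_warning(qp <- flow_rate_from_profile(r, rep(3, 513)), "wall")
  expect_equal(qp, pi * 0.2^2 * 3, tolerance = 1e-12)
  # Newtonian parabola
  u0 <- 8
  expect_equal(flow_rate_from_profile(r, u0 * (1 - (r / 0.2)^2)),
               pi * 0.2^2 * u0 / 2, tolerance = 1e-10)
  # solver self-consistency
  sol <- solve_flow_rate(power_law_params(0.45, 10), small_geometry(), 150)
  expect_equal(flow_rate_from_profile(sol$exit_profile$r_mm,
                                      sol$exit_profile$u_mm_s),
               sol$Q_ul_s, tolerance = 1e-4)
})

test_that("flow rate is monotone in pressure, K and n", {
  g <- small_geometry()
  Qp <- vapply(c(50, 150, 250, 350), function(P)
    solve_flow_rate(power_law_params(0.575, 55), g, P)$Q_ul_s, 0)
  expect_true(all(diff(Qp) > 0))
  QK <- vapply(c(10, 30, 60, 100), function(K)
    solve_flow_rate(power_law_params(0.575, K), g, 250)$Q_ul_s, 0)
  expect_true(all(diff(QK) < 0))
  # decreasing in n while the wall shear rate everywhere exceeds 1/s
  Qn <- vapply(c(0.45, 0.55, 0.65, 0.7), function(n) {
    s <- solve_flow_rate(power_law_params(n, 55), g, 250)
    expect_gt(s$wall_shear_rate_per_s, 1)
    s$Q_ul_s
  }, 0)
  expect_true(all(diff(Qn) < 0))
})

test_that("Q versus P is near-linear for nearly Newtonian fluids", {
  g <- small_geometry()
  P <- seq(50, 350, by = 50)
  Q <- vapply(P, function(p)
    solve_flow_rate(power_law_params(0.95, 40), g, p)$Q_ul_s, 0)
  r2 <- summary(lm(Q ~ P))$r.squared
  expect_gte(r2, 0.99)
})

test_that("exit velocity profiles have the power-law shape", {
  sol <- solve_flow_rate(power_law_params(0.575, 55), small_geometry(), 250)
  u <- sol$exit_profile$u_mm_s
  expect_equal(which.max(u), 1L)             # maximal on the axis
  expect_equal(u[length(u)], 0)              # no slip
  expect_true(all(diff(u) < 0))
  # profile flattens (plug-like) as n decreases at matched radius
  ratio <- function(n) {
    s <- solve_flow_rate(power_law_params(n, 55), small_geometry(), 250)
    mid <- ceiling(length(s$exit_profile$u_mm_s) / 2)
    s$exit_profile$u_mm_s[mid] / max(s$exit_profile$u_mm_s)
  }
  expect_gt(ratio(0.45), ratio(0.9))
})

test_that("filament diameter follows volume conservation", {
  expect_equal(filament_diameter(pi, 4), 1)
  expect_equal(filament_diameter(1, 48), filament_diameter(1, 12) / 2)
  # nozzle-matched flow: Q = area x speed reproduces the nozzle diameter
  v <- 12
  Q <- pi * 0.125^2 * v                       # uL/s == mm^3/s
  expect_equal(filament_diameter(Q, v), 0.25)
  expect_error(filament_diameter(0, 1), "Q")
  expect_error(filament_diameter(1, -1), "v")
})
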