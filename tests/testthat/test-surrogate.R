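test_that("Latin hypercube samples stratify every axis", {
  for (ns in c(1L, 7L, 300L)) {
    s <- latin_hypercube(n_samples = ns, seed = 31L)
    expect_equal(nrow(s$points), ns)
    for (d in names(s$bounds)) {
      lo <- s$bounds[[d]][1]; hi <- s$bounds[[d]][2]
      expect_true(all(s$points[[d]] > lo & s$points[[d]] < hi))
      stratum <- floor((s$points[[d]] - lo) / (hi - lo) * ns)
      expect_setequal(stratum, 0:(ns - 1L))   # exactly one point per stratum
    }
  }
  expect_identical(latin_hypercube(n_samples = 40, seed = 5)$points,
                   latin_hypercube(n_samples = 40, seed = 5)$points)
  expect_error(latin_hypercube(list(n = c(1, 1)), 10, 1), "degenerate")
  expect_error(latin_hypercube(n_samples = 0, seed = 1), ">= 1")
})

test_that("flow datasets are solved pointwise with monotone pressure response", {
  pts <- data.frame(n = rep(0.575, 4), K_pa_s = rep(55, 4),
                    P_kpa = c(50, 150, 250, 350))
  ds <- build_flow_dataset(pts, small_geometry())
  expect_true(all(is.finite(ds$Q_ul_s)))
  expect_length(attr(ds, "failures"), 0)
  expect_true(all(diff(ds$Q_ul_s) > 0))
  expect_error(build_flow_dataset(data.frame(x = 1)), "columns")
})

test_that("error reports compute MAE and RMSE with RMSE >= MAE", {
  e <- error_report(c(1, 2), c(1, 4))
  expect_equal(e$mae, 1)
  expect_equal(e$rmse, sqrt(2))
  perfect <- error_report(1:5, 1:5)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  single <- error_report(3, 2.25)
  expect_equal(single$mae, 0.75)
  expect_equal(single$rmse, 0.75)
  set.seed(8)
  for (i in 1:20) {
    y <- rnorm(30); yh <- y + rnorm(30)
    r <- error_report(y, yh)
    expect_gte(r$rmse, r$mae)
  }
  expect_error(error_report(numeric(0), numeric(0)), ">= 1")
})

test_that("surrogate training is deterministic and learns easy targets", {
  set.seed(99)
  pts <- data.frame(n = runif(60, 0.45, 0.7), K_pa_s = runif(60, 10, 100),
                    P_kpa = runif(60, 50, 350))
  pts$Q_ul_s <- 0.01 * pts$P_kpa              # noise-free linear target
  m1 <- train_surrogate(pts, seed = 4, restarts = 3L, maxit = 3000L)
  m2 <- train_surrogate(pts, seed = 4, restarts = 3L, maxit = 3000L)
  expect_identical(m1$fit$wts, m2$fit$wts)
  set.seed(100)
  test <- data.frame(n = runif(40, 0.46, 0.69), K_pa_s = runif(40, 11, 99),
                     P_kpa = runif(40, 60, 340))
  e <- evaluate_surrogate(m1, test, 0.01 * test$P_kpa)
  expect_lt(e$mae_pct, 0.5)
  expect_error(train_surrogate(pts[1:10, ]), ">= 30")
})

test_that("the RBF backend is deterministic and accurate on smooth surfaces", {
  set.seed(41)
  pts <- data.frame(n = runif(80, 0.45, 0.7), K_pa_s = runif(80, 10, 100),
                    P_kpa = runif(80, 50, 350))
  pts$Q_ul_s <- 0.5 + 0.01 * pts$P_kpa - 2 * pts$n
  m <- train_surrogate(pts, backend = "rbf", ridge = 1e-8,
                       log_response = FALSE)
  m2 <- train_surrogate(pts, backend = "rbf", ridge = 1e-8,
                        log_response = FALSE)
  expect_identical(m$fit$weights, m2$fit$weights)
  set.seed(42)
  test <- data.frame(n = runif(30, 0.5, 0.65), K_pa_s = runif(30, 20, 90),
                     P_kpa = runif(30, 100, 300))
  e <- evaluate_surrogate(m, test, 0.5 + 0.01 * test$P_kpa - 2 * test$n)
  expect_lt(e$mae_pct, 1)
})

test_that("surrogates flag extrapolation outside the training box", {
  set.seed(13)
  pts <- data.frame(n = runif(40, 0.5, 0.6), K_pa_s = runif(40, 30, 60),
                    P_kpa = runif(40, 100, 200))
  pts$Q_ul_s <- pts$P_kpa / 100
  m <- train_surrogate(pts, restarts = 2L, maxit = 1000L)
  expect_warning(p <- predict(m, data.frame(n = 0.7, K_pa_s = 45,
                                            P_kpa = 150)),
                 "outside the training box")
  expect_true(attr(p, "extrapolated"))
})

test_that("surrogate JSON serialization round-trips predictions", {
  set.seed(55)
  pts <- data.frame(n = runif(50, 0.45, 0.7), K_pa_s = runif(50, 10, 100),
                    P_kpa = runif(50, 50, 350))
  pts$Q_ul_s <- exp(1 - 2 * pts$n) * pts$P_kpa / 100
  m <- train_surrogate(pts, restarts = 2L, maxit = 2000L, seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  write_surrogate_json(m, f)
  back <- read_surrogate_json(f)
  newpts <- pts[1:10, 1:3]
  expect_equal(as.numeric(predict(back, newpts)),
               as.numeric(predict(m, newpts)), tolerance = 1e-10)
})

test_that("k-means regimes recover separated groups and order by flow rate", {
  set.seed(6)
  blob <- function(n0, K0, Q0) data.frame(
    n = n0 + runif(30, -0.01, 0.01), K_pa_s = K0 + runif(30, -1, 1),
    Q_ul_s = Q0 + runif(30, -0.01, 0.01))
  surf <- rbind(blob(0.5, 80, 0.05), blob(0.6, 50, 1), blob(0.65, 15, 4))
  lab <- classify_regimes(surf, seed = 2)
  expect_equal(as.character(lab$regime),
               rep(c("high-viscosity", "medium-viscosity", "low-viscosity"),
                   each = 30))
  lab2 <- classify_regimes(surf, seed = 2)
  expect_identical(lab$regime, lab2$regime)
  rg <- attr(lab, "regimes")
  expect_true(all(diff(rg$mean_Q) > 0))       # ordered by mean Q
  expect_error(classify_regimes(surf[1:2, ], k = 3), "k must not exceed")
})

test_that("flow surfaces shift up with pressure and steepen at low n and K", {
  s150 <- flow_surface(150, geometry = small_geometry(), grid_steps = 5)
  s300 <- flow_surface(300, geometry = small_geometry(), grid_steps = 5)
  expect_true(all(s300$Q_ul_s > s150$Q_ul_s))
  # steepest |dQ/dn| at the low-n, low-K edge
  g <- s150[order(s150$K_pa_s, s150$n), ]
  low_K <- g[g$K_pa_s == min(g$K_pa_s), ]
  high_K <- g[g$K_pa_s == max(g$K_pa_s), ]
  slope <- function(b) abs(diff(b$Q_ul_s)) / diff(b$n)
  expect_gt(slope(low_K)[1], max(slope(high_K)))
})

test_that("regime boundaries drift with extrusion pressure", {
  labels <- lapply(c(150, 200, 250, 300), function(P) {
    surf <- flow_surface(P, geometry = small_geometry(), grid_steps = 12)
    as.integer(classify_regimes(surf, seed = 4)$regime)
  })
  # same grid, different pressures: the partitions are not all identical
  expect_true(any(vapply(labels[-1], function(l)
    !identical(l, labels[[1]]), TRUE)))
})

test_that("surrogate error shrinks as the training set doubles", {
  # median test MAE over seeds for nested 75/150/300-point training sets
  maes <- vapply(1:6, function(s) {
    ds <- synth_flow_dataset(300, 30, geometry = small_geometry(),
                             seed = 777 + s)
    vapply(c(75, 150, 300), function(k) {
      m <- train_surrogate(ds$train[seq_len(k), ], seed = 777 + s,
                           restarts = 5L, maxit = 5000L)
      suppressWarnings(
        evaluate_surrogate(m, ds$test, ds$test$Q_ul_s))$mae_pct
    }, 0)
  }, c(0, 0, 0))
  med <- apply(maes, 1, median)
  expect_lt(med[3], med[1])
  expect_lte(med[3], med[2])
})
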