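#' Default sampling box for the flow-rate study
#'
#' Power-law index 0.45-0.7, consistency coefficient 10-100 Pa.s, extrusion
#' pressure 50-350 kPa: the printable-ink window established by the
#' response-surface stage.
#'
#' @return Named list of `c(low, high)` bounds for `n`, `K_pa_s`, `P_kpa`.
#' @export
default_flow_bounds <- function() {
  list(n = c(0.45, 0.7), K_pa_s = c(10, 100), P_kpa = c(50, 350))
}

#' Latin hypercube sample over a box
#'
#' Space-filling sample with exactly one point per equal stratum on every
#' axis, reproducible by seed.
#'
#' @param bounds Named list of `c(low, high)` per dimension
#'   (default [default_flow_bounds()]).
#' @param n_samples Number of points (>= 1).
#' @param seed Integer seed.
#' @return An object of class `sample_set`: `points` (data frame, one column
#'   per dimension), `bounds`, `seed`.
#' @export
latin_hypercube <- function(bounds = default_flow_bounds(), n_samples, seed) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  lo <- vapply(bounds, `[`, 0, 1)
  hi <- vapply(bounds, `[`, 0, 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("degenerate bounds: each dimension needs low < high")
  set.seed(seed)
  u <- lhs::randomLHS(n_samples, length(bounds))
  pts <- as.data.frame(sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  names(pts) <- names(bounds)
  structure(list(points = pts, bounds = bounds, seed = as.integer(seed)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("Sample set: %d points over %s (seed %d)%s\n",
              nrow(x$points), paste(names(x$bounds), collapse = ", "),
              x$seed,
              if ("Q_ul_s" %in% names(x$points)) ", flow rates evaluated" else ""))
  invisible(x)
}

#' Evaluate the nozzle solver over a sample set
#'
#' Fills a `Q_ul_s` column by running [solve_flow_rate()] at each sampled
#' (n, K, P) point. Solver failures are recorded per point (Q set to NA and
#' the index kept in the `failures` attribute), never silently dropped.
#'
#' @param samples A [latin_hypercube()] sample set with columns `n`, `K_pa_s`,
#'   `P_kpa` (or any data frame with those columns).
#' @param geometry A [nozzle_geometry()].
#' @return The sample set with `Q_ul_s` filled and attribute `failures`.
#' @export
build_flow_dataset <- function(samples, geometry = default_nozzle_geometry()) {
  pts <- if (inherits(samples, "sample_set")) samples$points else
    as.data.frame(samples)
  need <- c("n", "K_pa_s", "P_kpa")
  if (!all(need %in% names(pts)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  Q <- rep(NA_real_, nrow(pts))
  fails <- list()
  for (i in seq_len(nrow(pts))) {
    res <- tryCatch(
      solve_flow_rate(power_law_params(pts$n[i], pts$K_pa_s[i]), geometry,
                      pts$P_kpa[i])$Q_ul_s,
      error = function(e) e)
    if (inherits(res, "error")) fails[[length(fails) + 1L]] <-
        list(index = i, message = conditionMessage(res))
    else Q[i] <- res
  }
  pts$Q_ul_s <- Q
  if (inherits(samples, "sample_set")) {
    samples$points <- pts
    attr(samples, "failures") <- fails
    return(samples)
  }
  attr(pts, "failures") <- fails
  pts
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

standardize_apply <- function(X, z) sweep(sweep(X, 2, z$mu, "-"), 2, z$sd, "/")

#' Train a flow-rate surrogate
#'
#' Fits a cheap approximator of Q(n, K, P) to solver outputs. The default
#' backend is a single-hidden-layer feed-forward network (logistic hidden
#' units, linear output) with an L2 (ridge) weight penalty, trained
#' deterministically under the given seed; an alternative Gaussian
#' radial-basis interpolator with ridge regularization is available under the
#' same interface. Inputs are standardized to zero mean and unit variance on
#' the training set; the response is standardized likewise.
#'
#' @param dataset A sample set (or data frame) with columns `n`, `K_pa_s`,
#'   `P_kpa`, `Q_ul_s` and no missing flow rates; >= 30 points.
#' @param hidden_units Hidden-layer size (nnet backend).
#' @param ridge L2 penalty (nnet `decay`, or RBF ridge).
#' @param seed Integer seed (weight initialization).
#' @param backend `"nnet"` (default) or `"rbf"`.
#' @param maxit Maximum training iterations (nnet backend).
#' @param restarts Random weight restarts; the fit with the lowest training
#'   loss is kept (the flow surface spans decades, so single starts can land
#'   in poor local minima). Deterministic given the seed.
#' @param log_response Model log(Q) instead of Q (default `TRUE`): the flow
#'   rate is positive and spans decades over the printable box, so the log
#'   surface is far smoother. Requires strictly positive training flow rates.
#' @return An object of class `flow_surrogate`.
#' @export
train_surrogate <- function(dataset, hidden_units = 8L, ridge = 1e-5, seed = 1L,
                            backend = c("nnet", "rbf"), maxit = 10000L,
                            restarts = 10L, log_response = TRUE) {
  backend <- match.arg(backend)
  pts <- if (inherits(dataset, "sample_set")) dataset$points else
    as.data.frame(dataset)
  need <- c("n", "K_pa_s", "P_kpa", "Q_ul_s")
  if (!all(need %in% names(pts)))
    stop("dataset must have columns: ", paste(need, collapse = ", "))
  if (anyNA(pts$Q_ul_s)) stop("dataset contains unsolved (NA) flow rates")
  if (nrow(pts) < 30L) stop("need >= 30 training points")
  X <- as.matrix(pts[c("n", "K_pa_s", "P_kpa")])
  y <- pts$Q_ul_s
  if (log_response) {
    if (any(y <= 0))
      stop("log_response requires strictly positive flow rates; ",
           "set log_response = FALSE for data with non-positive Q")
    y <- log(y)
  }
  zx <- standardize_fit(X)
  Xs <- standardize_apply(X, zx)
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  box <- apply(X, 2, range)

  if (backend == "nnet") {
    set.seed(seed)
    net <- NULL
    for (r in seq_len(max(1L, restarts))) {
      cand <- nnet::nnet(Xs, ys, size = hidden_units, decay = ridge,
                         linout = TRUE, maxit = maxit, trace = FALSE)
      if (is.null(net) || cand$value < net$value) net <- cand
    }
    loss <- net$value
    if (!is.finite(loss)) stop("training divergence: non-finite loss")
    fitobj <- net
  } else {
    D2 <- as.matrix(stats::dist(Xs))^2
    bw <- stats::median(D2[upper.tri(D2)])
    if (!is.finite(bw) || bw <= 0) bw <- 1
    Phi <- exp(-D2 / bw)
    w <- solve(Phi + ridge * diag(nrow(Phi)), ys)
    loss <- mean((Phi %*% w - ys)^2)
    fitobj <- list(centers = Xs, weights = w, bandwidth = bw)
  }
  structure(list(
    backend = backend, fit = fitobj, loss = loss,
    x_norm = zx, y_mu = mu_y, y_sd = sd_y, log_response = log_response,
    box = box, seed = as.integer(seed),
    hidden_units = as.integer(hidden_units), ridge = ridge
  ), class = "flow_surrogate")
}

#' Predict flow rates from a trained surrogate
#'
#' Deterministic polynomial-free evaluation of the stored weights. Points
#' outside the training box are flagged (attribute `extrapolated`, plus a
#' warning), since the surrogate is only trusted inside it.
#'
#' @param object A [train_surrogate()] model.
#' @param newdata Data frame with columns `n`, `K_pa_s`, `P_kpa`.
#' @param ... Unused.
#' @return Numeric vector of predicted Q, uL/s, with logical attribute
#'   `extrapolated` per row.
#' @export
predict.flow_surrogate <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  X <- as.matrix(newdata[c("n", "K_pa_s", "P_kpa")])
  outside <- rowSums(sweep(X, 2, object$box[1, ], "<") |
                       sweep(X, 2, object$box[2, ], ">")) > 0
  if (any(outside))
    warning(sum(outside), " point(s) outside the training box; ",
            "surrogate extrapolates there")
  Xs <- standardize_apply(X, object$x_norm)
  ys <- if (object$backend == "nnet") {
    drop(stats::predict(object$fit, Xs))
  } else {
    D2 <- outer(rowSums(Xs^2), rowSums(object$fit$centers^2), "+") -
      2 * Xs %*% t(object$fit$centers)
    drop(exp(-pmax(D2, 0) / object$fit$bandwidth) %*% object$fit$weights)
  }
  out <- ys * object$y_sd + object$y_mu
  if (isTRUE(object$log_response)) out <- exp(out)
  attr(out, "extrapolated") <- outside
  out
}

#' @export
print.flow_surrogate <- function(x, ...) {
  cat(sprintf("Flow-rate surrogate (%s backend%s, ridge %g, seed %d)\n",
              x$backend,
              if (x$backend == "nnet") sprintf(", %d hidden units", x$hidden_units) else "",
              x$ridge, x$seed))
  invisible(x)
}

#' Prediction-error report (MAE / RMSE)
#'
#' Mean absolute error \eqn{\frac{1}{n}\sum|y_i - \hat y_i|} and
#' root-mean-square error \eqn{\sqrt{\frac{1}{n}\sum(y_i - \hat y_i)^2}},
#' reported both raw and as a percentage of the observed range of `observed`
#' (the normalization basis).
#'
#' @param observed Reference values y.
#' @param predicted Predictions y-hat (same length).
#' @return An object of class `surrogate_errors`: `mae`, `rmse`, `mae_pct`,
#'   `rmse_pct`, `q_range`, `residuals`, `n_test`.
#' @export
error_report <- function(observed, predicted) {
  if (length(observed) < 1L || length(observed) != length(predicted))
    stop("need >= 1 observation with one prediction each")
  resid <- observed - as.numeric(predicted)
  mae <- mean(abs(resid))
  rmse <- sqrt(mean(resid^2))
  q_range <- diff(range(observed))
  structure(list(
    mae = mae, rmse = rmse,
    mae_pct = if (q_range > 0) 100 * mae / q_range else NA_real_,
    rmse_pct = if (q_range > 0) 100 * rmse / q_range else NA_real_,
    q_range = q_range, residuals = resid, n_test = length(resid)
  ), class = "surrogate_errors")
}

#' Score a surrogate on held-out points
#'
#' Evaluates the surrogate at the test points and reports MAE/RMSE against
#' the reference flow rates via [error_report()].
#'
#' @param model A [train_surrogate()] model.
#' @param test_points Data frame with columns `n`, `K_pa_s`, `P_kpa`.
#' @param true_Q Reference flow rates, uL/s (same length).
#' @return A `surrogate_errors` report.
#' @export
evaluate_surrogate <- function(model, test_points, true_Q) {
  test_points <- as.data.frame(test_points)
  if (nrow(test_points) < 1L || length(true_Q) != nrow(test_points))
    stop("need >= 1 test point with one reference Q each")
  error_report(true_Q, predict(model, test_points))
}

#' @export
print.surrogate_errors <- function(x, ...) {
  cat(sprintf("Surrogate errors on %d test points: MAE = %.4g uL/s (%.2f%% of range), RMSE = %.4g uL/s (%.2f%% of range)\n",
              x$n_test, x$mae, x$mae_pct, x$rmse, x$rmse_pct))
  invisible(x)
}

# k-means++ center seeding (deterministic given the RNG state)
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ], "-")^2))
  }
  centers
}

#' Partition a flow-rate surface into viscosity regimes
#'
#' k-means (k = 3 by default) on standardized (n, K, Q) features of a flow
#' surface at fixed pressure, with k-means++-style seeding under a fixed
#' seed. Clusters are ordered by mean flow rate and labelled
#' `high-viscosity` (lowest Q), `medium-viscosity`, `low-viscosity`
#' (highest Q), so labels do not depend on arbitrary cluster indices.
#'
#' @param surface Data frame with columns `n`, `K_pa_s`, `Q_ul_s`.
#' @param k Number of regimes (default 3).
#' @param seed Integer seed.
#' @return The surface with columns `regime` (ordered factor) and `cluster`
#'   appended; cluster summary in attribute `regimes`.
#' @export
classify_regimes <- function(surface, k = 3L, seed = 1L) {
  surface <- as.data.frame(surface)
  need <- c("n", "K_pa_s", "Q_ul_s")
  if (!all(need %in% names(surface)))
    stop("surface must have columns: ", paste(need, collapse = ", "))
  if (nrow(surface) < k) stop("k must not exceed the number of points")
  X <- as.matrix(surface[need])
  z <- standardize_fit(X)
  Xs <- standardize_apply(X, z)
  set.seed(seed)
  km <- stats::kmeans(Xs, centers = kmeanspp_centers(Xs, k), iter.max = 100L)
  meanQ <- tapply(surface$Q_ul_s, km$cluster, mean)
  ord <- order(meanQ)                       # lowest Q first = highest viscosity
  labels <- if (k == 3L)
    c("high-viscosity", "medium-viscosity", "low-viscosity") else
      paste0("regime-", seq_len(k))
  lab_by_cluster <- character(k)
  lab_by_cluster[ord] <- labels
  surface$cluster <- km$cluster
  surface$regime <- factor(lab_by_cluster[km$cluster], levels = labels)
  attr(surface, "regimes") <- data.frame(
    regime = labels,
    cluster = ord,
    mean_Q = as.numeric(meanQ[ord]),
    var_Q = as.numeric(tapply(surface$Q_ul_s, km$cluster, stats::var)[ord]),
    size = as.numeric(table(km$cluster)[ord])
  )
  surface
}

#' Tabulate the flow-rate surface over the (n, K) plane
#'
#' Evaluates flow rate on a regular (n, K) grid at fixed pressure, using
#' either the physical solver or a trained surrogate.
#'
#' @param pressure Extrusion pressure, kPa.
#' @param n_grid,K_grid Grid vectors; defaults span [default_flow_bounds()].
#' @param model Optional [train_surrogate()] model; if `NULL`, the solver is
#'   used.
#' @param geometry A [nozzle_geometry()] (solver mode).
#' @param grid_steps Points per axis when grids are not supplied.
#' @return Data frame `n`, `K_pa_s`, `P_kpa`, `Q_ul_s` (plus `extrapolated`
#'   in surrogate mode).
#' @export
flow_surface <- function(pressure, model = NULL,
                         geometry = default_nozzle_geometry(),
                         grid_steps = 20L,
                         n_grid = NULL, K_grid = NULL) {
  b <- default_flow_bounds()
  if (is.null(n_grid)) n_grid <- seq(b$n[1], b$n[2], length.out = grid_steps)
  if (is.null(K_grid)) K_grid <- seq(b$K_pa_s[1], b$K_pa_s[2],
                                     length.out = grid_steps)
  g <- expand.grid(n = n_grid, K_pa_s = K_grid)
  g$P_kpa <- pressure
  if (is.null(model)) {
    g <- build_flow_dataset(g, geometry)
  } else {
    pred <- predict(model, g)
    g$Q_ul_s <- as.numeric(pred)
    g$extrapolated <- attr(pred, "extrapolated")
  }
  g
}

#' Read / write flow-rate dataset CSV files
#'
#' Columns `n, K_pa_s, P_kpa, Q_ul_s`.
#'
#' @param path File path.
#' @return A data frame with those columns.
#' @export
read_flow_dataset <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("n", "K_pa_s", "P_kpa", "Q_ul_s")
  if (!all(need %in% names(df)))
    stop("flow dataset CSV must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' @param dataset A data frame (or sample set) with the dataset columns.
#' @rdname read_flow_dataset
#' @export
write_flow_dataset <- function(dataset, path) {
  pts <- if (inherits(dataset, "sample_set")) dataset$points else dataset
  utils::write.csv(pts, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize / restore a surrogate model as JSON
#'
#' Stores weights, normalization parameters, training box and seed so a
#' trained surrogate can be archived and re-loaded without retraining.
#'
#' @param model A [train_surrogate()] model.
#' @param path JSON file path.
#' @return `write_surrogate_json()` the path invisibly;
#'   `read_surrogate_json()` a `flow_surrogate`.
#' @export
write_surrogate_json <- function(model, path) {
  stopifnot(inherits(model, "flow_surrogate"))
  out <- list(
    backend = model$backend,
    x_mu = as.list(model$x_norm$mu), x_sd = as.list(model$x_norm$sd),
    y_mu = model$y_mu, y_sd = model$y_sd,
    log_response = model$log_response,
    box = as.data.frame(model$box),
    seed = model$seed, hidden_units = model$hidden_units, ridge = model$ridge,
    loss = model$loss
  )
  if (model$backend == "nnet") {
    out$wts <- model$fit$wts
    out$n_struct <- model$fit$n
  } else {
    out$centers <- as.data.frame(model$fit$centers)
    out$weights <- as.numeric(model$fit$weights)
    out$bandwidth <- model$fit$bandwidth
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate_json
#' @export
read_surrogate_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- if (s$backend == "nnet") {
    net <- structure(list(n = s$n_struct, wts = s$wts, nunits = sum(s$n_struct) + 1L,
                          decay = s$ridge), class = "nnet")
    # rebuild the connection bookkeeping nnet needs for prediction
    skel <- nnet::nnet(matrix(0, 4, s$n_struct[1]), rep(0, 4),
                       size = s$n_struct[2], linout = TRUE, maxit = 1L,
                       trace = FALSE)
    skel$wts <- s$wts
    skel
  } else {
    list(centers = as.matrix(s$centers), weights = s$weights,
         bandwidth = s$bandwidth)
  }
  structure(list(
    backend = s$backend, fit = fit, loss = s$loss,
    x_norm = list(mu = unlist(s$x_mu), sd = unlist(s$x_sd)),
    y_mu = s$y_mu, y_sd = s$y_sd, log_response = isTRUE(s$log_response),
    box = as.matrix(s$box), seed = as.integer(s$seed),
    hidden_units = as.integer(s$hidden_units), ridge = s$ridge
  ), class = "flow_surrogate")
}
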