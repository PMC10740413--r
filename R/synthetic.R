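#' Synthetic-data generator settings
#'
#' Noise model and grids for the synthetic inputs that emulate the measurement
#' protocol: multiplicative log-normal noise on viscosity readings (rheometer
#' error scales with the reading), additive Gaussian noise on the design
#' responses n and K. Default magnitudes (sigma_log = 0.03, sigma_n = 0.005,
#' sigma_K = 2 Pa.s) are conventions chosen to emulate validation-table-like
#' prediction accuracy; true instrument error magnitudes are not modelled.
#'
#' @param seed Integer seed recorded in all outputs.
#' @param sigma_log Log-scale SD of multiplicative viscosity noise (>= 0).
#' @param sigma_n SD of additive noise on the power-law index (>= 0).
#' @param sigma_K SD of additive noise on the consistency coefficient,
#'   Pa.s (>= 0).
#' @param n_points Number of shear-rate points per curve (default 21).
#' @param shear_range Shear-rate range, 1/s (default 1-100).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, sigma_log = 0.03, sigma_n = 0.005,
                         sigma_K = 2, n_points = 21L,
                         shear_range = c(1, 100)) {
  if (any(c(sigma_log, sigma_n, sigma_K) < 0)) stop("noise sigmas must be >= 0")
  if (n_points < 2L) stop("n_points must be >= 2")
  if (shear_range[1] <= 0 || shear_range[2] <= shear_range[1])
    stop("shear_range must be increasing and positive")
  structure(list(seed = as.integer(seed), sigma_log = sigma_log,
                 sigma_n = sigma_n, sigma_K = sigma_K,
                 n_points = as.integer(n_points), shear_range = shear_range),
            class = "synth_config")
}

#' Synthesize a rheometry flow curve for an ink composition
#'
#' Ground-truth (n, K) come from the published response models
#' ([predict_n()], [predict_K()]); shear rates are endpoint-inclusive and
#' log-uniformly spaced (constant ratio between consecutive points);
#' viscosities follow the power law times multiplicative log-normal noise.
#' Deterministic under the config seed.
#'
#' @param ratio A composition (see [composition_ratio()]).
#' @param config A [synth_config()].
#' @return A [shear_viscosity_curve()] with attribute `truth`
#'   (the generating [power_law_params()]) and `seed`.
#' @export
synth_rheometry <- function(ratio, config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  comp <- as_composition(ratio)
  if (nrow(comp) != 1L) stop("one composition at a time")
  truth <- power_law_params(predict_n(comp), predict_K(comp))
  g <- exp(seq(log(config$shear_range[1]), log(config$shear_range[2]),
               length.out = config$n_points))
  set.seed(config$seed)
  eta <- power_law_viscosity(truth, g) *
    exp(stats::rnorm(config$n_points, 0, config$sigma_log))
  curve <- shear_viscosity_curve(g, eta, temperature = 30)
  attr(curve, "truth") <- truth
  attr(curve, "seed") <- config$seed
  curve
}

#' Synthesize Box-Behnken design responses
#'
#' Per-run true n and K from the published response models plus seeded
#' additive Gaussian noise. The generating truth is attached for recovery
#' tests; center replicates are identical at zero noise.
#'
#' @param design A [bb_design()] over Gel/SA/MC.
#' @param sigma_n,sigma_K Additive noise SDs (default from [synth_config()]).
#' @param seed Integer seed.
#' @return Data frame `run, gel_wtpct, sa_wtpct, mc_wtpct, n, K_pa_s` with
#'   attributes `truth_n`, `truth_K`, `seed`.
#' @export
synth_bb_responses <- function(design, sigma_n = 0.005, sigma_K = 2,
                               seed = 1L) {
  stopifnot(inherits(design, "bb_design"))
  comp <- composition_ratio(design$uncoded$Gel, design$uncoded$SA,
                            design$uncoded$MC)
  true_n <- predict_n(comp)
  true_K <- predict_K(comp)
  m <- nrow(design$coded)
  set.seed(seed)
  out <- data.frame(
    run = seq_len(m),
    gel_wtpct = design$uncoded$Gel,
    sa_wtpct = design$uncoded$SA,
    mc_wtpct = design$uncoded$MC,
    n = true_n + stats::rnorm(m, 0, sigma_n),
    K_pa_s = true_K + stats::rnorm(m, 0, sigma_K)
  )
  attr(out, "truth_n") <- true_n
  attr(out, "truth_K") <- true_K
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Synthesize a flow-rate training/testing dataset
#'
#' Mirrors the simulation protocol: a Latin-hypercube training set plus a
#' uniform-random test set over the (n, K, P) box, flow rates computed by the
#' nozzle solver, with optional additive Gaussian noise.
#'
#' @param n_train Training points (LHS; default 300).
#' @param n_test Test points (uniform random; default 50; 0 to skip).
#' @param bounds Sampling box (default [default_flow_bounds()]).
#' @param geometry A [nozzle_geometry()].
#' @param sigma_Q Additive noise SD on Q, uL/s (default 0).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, each a data frame
#'   `n, K_pa_s, P_kpa, Q_ul_s`; attribute `seed`.
#' @export
synth_flow_dataset <- function(n_train = 300L, n_test = 50L,
                               bounds = default_flow_bounds(),
                               geometry = default_nozzle_geometry(),
                               sigma_Q = 0, seed = 1L) {
  if (n_train < 1L) stop("n_train must be >= 1")
  if (sigma_Q < 0) stop("sigma_Q must be >= 0")
  train <- build_flow_dataset(latin_hypercube(bounds, n_train, seed),
                              geometry)$points
  test <- NULL
  if (n_test > 0L) {
    set.seed(seed + 1L)
    lo <- vapply(bounds, `[`, 0, 1)
    hi <- vapply(bounds, `[`, 0, 2)
    u <- matrix(stats::runif(n_test * length(bounds)), n_test)
    pts <- as.data.frame(sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
    names(pts) <- names(bounds)
    names(pts) <- c("n", "K_pa_s", "P_kpa")
    test <- build_flow_dataset(pts, geometry)
  }
  if (sigma_Q > 0) {
    set.seed(seed + 2L)
    train$Q_ul_s <- train$Q_ul_s + stats::rnorm(nrow(train), 0, sigma_Q)
    if (!is.null(test))
      test$Q_ul_s <- test$Q_ul_s + stats::rnorm(nrow(test), 0, sigma_Q)
  }
  out <- list(train = train, test = test)
  attr(out, "seed") <- as.integer(seed)
  out
}
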