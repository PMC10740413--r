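#' Default end-to-end pipeline configuration
#'
#' The study conditions of the whole workflow: reference compositions, the
#' Box-Behnken design, the default nozzle geometry, the 300-train / 50-test
#' sampling protocol over the printable (n, K, P) box, surrogate
#' hyperparameters, regime classification pressures and the print-job
#' parameters. One master seed deterministically derives all stage seeds.
#'
#' @param seed Master seed.
#' @param output_dir Run directory (created by [run_pipeline()]).
#' @return A nested configuration list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L, output_dir = "inkflow-run") {
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    geometry = list(
      length_mm = c(10, 20, 25),
      r_in_mm = c(4.8, 4.8, 0.125),
      r_out_mm = c(4.8, 0.125, 0.125)
    ),
    synth = list(sigma_log = 0.03, sigma_n = 0.005, sigma_K = 2),
    rsm = list(center_replicates = 5L, alpha = 0.05),
    sampling = list(
      n_bounds = c(0.45, 0.7),
      K_bounds = c(10, 100),
      P_bounds = c(50, 350),
      n_train = 300L,
      n_test = 50L
    ),
    surrogate = list(hidden_units = 8L, ridge = 1e-5, maxit = 10000L,
                     restarts = 10L),
    regimes = list(pressure_kpa = 250, grid_steps = 15L),
    path = list(
      part_mm = c(10, 10, 3),
      pattern = "grid",
      speed = 12, slow_speed = 1, slow_time = 0.1,
      layer_thickness = 0.2, fill_spacing = 0.8,
      frame_offset = 0.5, overlap_d2 = 0.3,
      nozzle_diameter = 0.25, travel_speed = 30,
      pressure_kpa = 250
    )
  ), class = "pipeline_config")
}

# allowed keys per section (unknown keys are rejected)
config_schema <- function() {
  list(
    seed = NULL, output_dir = NULL,
    geometry = c("length_mm", "r_in_mm", "r_out_mm"),
    synth = c("sigma_log", "sigma_n", "sigma_K"),
    rsm = c("center_replicates", "alpha"),
    sampling = c("n_bounds", "K_bounds", "P_bounds", "n_train", "n_test"),
    surrogate = c("hidden_units", "ridge", "maxit", "restarts"),
    regimes = c("pressure_kpa", "grid_steps"),
    path = c("part_mm", "pattern", "speed", "slow_speed", "slow_time",
             "layer_thickness", "fill_spacing", "frame_offset", "overlap_d2",
             "nozzle_diameter", "travel_speed", "pressure_kpa")
  )
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys, checks required sections and checks that every
#' sampling bound is increasing. Called by [run_pipeline()] and
#' [read_pipeline_config()].
#'
#' @param config A configuration list.
#' @return The validated config (class `pipeline_config`), invisibly errors
#'   otherwise.
#' @export
validate_pipeline_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(schema), names(config))
  if (length(missing))
    stop("missing config section(s): ", paste(missing, collapse = ", "))
  for (sec in names(schema)) {
    if (is.null(schema[[sec]])) next
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  for (b in c("n_bounds", "K_bounds", "P_bounds")) {
    v <- config$sampling[[b]]
    if (length(v) != 2 || !all(is.finite(v)) || v[1] >= v[2])
      stop("config field sampling$", b, " must be an increasing (low, high) pair")
  }
  if (!is.finite(config$seed)) stop("config field seed must be an integer")
  class(config) <- "pipeline_config"
  config
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @param config A `pipeline_config`.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_geometry <- function(config) {
  nozzle_geometry(data.frame(length_mm = config$geometry$length_mm,
                             r_in_mm = config$geometry$r_in_mm,
                             r_out_mm = config$geometry$r_out_mm))
}

config_path <- function(config) {
  p <- config$path
  path_config(speed = p$speed, slow_speed = p$slow_speed,
              slow_time = p$slow_time, layer_thickness = p$layer_thickness,
              fill_spacing = p$fill_spacing, frame_offset = p$frame_offset,
              overlap_d2 = p$overlap_d2, nozzle_diameter = p$nozzle_diameter,
              travel_speed = p$travel_speed)
}

# stage seeds derived deterministically from the master seed
stage_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8L)
  names(s) <- c("rheometry", "responses", "sampling", "surrogate",
                "regimes", "reserve1", "reserve2", "reserve3")
  s
}

#' Run the full composition-to-toolpath pipeline
#'
#' Executes every stage in order -- synthetic rheometry + power-law fits,
#' Box-Behnken response modelling with backward elimination, validation-style
#' predictions, feasible-region enumeration, nozzle-flow dataset generation,
#' surrogate training and scoring, regime classification, flow-surface
#' tabulation, and toolpath planning with G-code export -- writing all
#' artifacts, the resolved configuration and a hash manifest into the run
#' directory. Deterministic given the master seed: rerunning with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config A `pipeline_config` (default [default_pipeline_config()]).
#' @return The run directory path, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  config <- validate_pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  seeds <- stage_seeds(config$seed)
  geometry <- config_geometry(config)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # 1. synthetic rheometry + power-law fits for the reference inks
  run_stage("rheometry", {
    refs <- data.frame(Gel = c(7, 8, 9), SA = 4, MC = 3)
    rows <- lapply(seq_len(nrow(refs)), function(i) {
      cfg <- synth_config(seed = seeds[["rheometry"]] %% 100000L + i,
                          sigma_log = config$synth$sigma_log)
      curve <- synth_rheometry(refs[i, ], cfg)
      fit <- fit_power_law(curve)
      truth <- attr(curve, "truth")
      data.frame(gel_wtpct = refs$Gel[i], sa_wtpct = refs$SA[i],
                 mc_wtpct = refs$MC[i],
                 n_true = truth$n, K_true = truth$K,
                 n_fit = fit$params$n, K_fit = fit$params$K,
                 r_squared = fit$r_squared)
    })
    utils::write.csv(do.call(rbind, rows), out("rheology_fits.csv"),
                     row.names = FALSE)
  })

  # 2. Box-Behnken design, synthetic responses, fitted + reduced models
  run_stage("rsm", {
    design <- bb_design_ink(config$rsm$center_replicates)
    resp <- synth_bb_responses(design, config$synth$sigma_n,
                               config$synth$sigma_K,
                               seed = seeds[["responses"]])
    write_design_responses(resp, out("design_responses.csv"))
    fit_n <- backward_eliminate(design, resp$n, alpha = config$rsm$alpha,
                                response_name = "n")
    fit_K <- backward_eliminate(design, resp$K_pa_s, alpha = config$rsm$alpha,
                                response_name = "K")
    write_model_json(fit_n, out("model_n.json"))
    write_model_json(fit_K, out("model_K.json"))
    # validation-style prediction table at the published check compositions
    val <- composition_ratio(c(10, 6, 7, 7.5, 9), c(4, 5, 4, 3, 5),
                             c(3, 4, 4, 2, 3))
    utils::write.csv(
      data.frame(val, n_pred = round(predict_n(val), 2),
                 K_pred_pa_s = round(predict_K(val), 2)),
      out("predictions.csv"), row.names = FALSE)
    utils::write.csv(enumerate_feasible_region(9L), out("feasible_region.csv"),
                     row.names = FALSE)
  })

  # 3. flow dataset + surrogate + errors
  bounds <- list(n = config$sampling$n_bounds,
                 K_pa_s = config$sampling$K_bounds,
                 P_kpa = config$sampling$P_bounds)
  ds <- run_stage("flow dataset", {
    d <- synth_flow_dataset(config$sampling$n_train, config$sampling$n_test,
                            bounds, geometry, sigma_Q = 0,
                            seed = seeds[["sampling"]])
    write_flow_dataset(d$train, out("flow_train.csv"))
    write_flow_dataset(d$test, out("flow_test.csv"))
    d
  })
  model <- run_stage("surrogate", {
    m <- train_surrogate(ds$train, config$surrogate$hidden_units,
                         config$surrogate$ridge, seed = seeds[["surrogate"]],
                         maxit = config$surrogate$maxit,
                         restarts = config$surrogate$restarts)
    write_surrogate_json(m, out("surrogate.json"))
    err <- evaluate_surrogate(m, ds$test, ds$test$Q_ul_s)
    jsonlite::write_json(
      list(mae_ul_s = err$mae, rmse_ul_s = err$rmse,
           mae_pct_of_range = err$mae_pct, rmse_pct_of_range = err$rmse_pct,
           q_range_ul_s = err$q_range, n_test = err$n_test),
      out("surrogate_errors.json"), auto_unbox = TRUE, digits = NA)
    m
  })

  # 4. regimes + solver-vs-surrogate surface at the reference pressure
  run_stage("regimes", {
    surf <- flow_surface(config$regimes$pressure_kpa, geometry = geometry,
                         grid_steps = config$regimes$grid_steps)
    lab <- classify_regimes(surf, seed = seeds[["regimes"]])
    utils::write.csv(lab, out("regimes.csv"), row.names = FALSE)
    utils::write.csv(attr(lab, "regimes"), out("regime_summary.csv"),
                     row.names = FALSE)
    pred <- predict(model, surf)
    surf$Q_surrogate <- as.numeric(pred)
    utils::write.csv(surf, out("surface.csv"), row.names = FALSE)
  })

  # 5. toolpath for the configured part + extrusion bookkeeping
  run_stage("pathplan", {
    pcfg <- config_path(config)
    part <- config$path$part_mm
    layers <- max(1L, round(part[3] / pcfg$layer_thickness))
    tp <- plan_grid_prism(part[1], part[2], layers, pcfg,
                          pattern = config$path$pattern)
    export_gcode(tp, out("toolpath.gcode"))
    sol <- solve_flow_rate(
      power_law_params(predict_n(c(8, 4, 3)), predict_K(c(8, 4, 3))),
      geometry, config$path$pressure_kpa)
    book <- extrusion_bookkeeping(tp, sol$Q_ul_s)
    utils::write.csv(book, out("path_segments.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(Q_ul_s = sol$Q_ul_s, pressure_kpa = config$path$pressure_kpa,
           layers = layers,
           printed_mm = sum(book$length_mm[book$extruding]),
           travel_mm = sum(book$length_mm[!book$extruding]),
           volume_ul = sum(book$volume_ul),
           slow_starts = sum(book$slow_start)),
      out("path_stats.json"), auto_unbox = TRUE, digits = NA)
  })

  # resolved config + manifest with content hashes
  write_pipeline_config(config, out("config.yaml"))
  files <- sort(setdiff(list.files(config$output_dir), "manifest.json"))
  hashes <- tools::md5sum(file.path(config$output_dir, files))
  jsonlite::write_json(
    list(seed = config$seed,
         files = data.frame(file = files, md5 = unname(hashes))),
    out("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(config$output_dir)
}

#' Summarize a completed pipeline run
#'
#' Pure-read tabulation of a run directory: the validation-style composition
#' predictions, surrogate errors, regime summary and toolpath statistics.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return A list of class `pipeline_report` (printed as a readable summary).
#' @export
report_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json in '", run_dir, "': not a completed run directory")
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  structure(list(
    run_dir = run_dir,
    seed = manifest$seed,
    predictions = utils::read.csv(file.path(run_dir, "predictions.csv")),
    rheology = utils::read.csv(file.path(run_dir, "rheology_fits.csv")),
    surrogate_errors = jsonlite::read_json(
      file.path(run_dir, "surrogate_errors.json"), simplifyVector = TRUE),
    regimes = utils::read.csv(file.path(run_dir, "regime_summary.csv")),
    path_stats = jsonlite::read_json(file.path(run_dir, "path_stats.json"),
                                     simplifyVector = TRUE)
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run:", x$run_dir, "(seed", x$seed, ")\n\n")
  cat("Composition predictions (published response models):\n")
  print(x$predictions, row.names = FALSE)
  cat(sprintf("\nSurrogate: MAE %.3f%% / RMSE %.3f%% of the test Q range (%d points)\n",
              x$surrogate_errors$mae_pct_of_range,
              x$surrogate_errors$rmse_pct_of_range,
              x$surrogate_errors$n_test))
  cat("\nViscosity regimes:\n")
  print(x$regimes, row.names = FALSE)
  cat(sprintf("\nToolpath: %.1f mm printed over %d layers, %.3g uL deposited, %d slow-start strokes\n",
              x$path_stats$printed_mm, x$path_stats$layers,
              x$path_stats$volume_ul, x$path_stats$slow_starts))
  invisible(x)
}
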