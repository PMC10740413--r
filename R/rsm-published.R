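#' Ink composition ratio
#'
#' A gelatin : sodium alginate : methylcellulose composition in wt%. Values
#' outside the response-surface design cube (Gel 6-10, SA 3-5, MC 2-4 wt%)
#' are allowed but trigger a warning, since the response models extrapolate
#' there. Vectorized.
#'
#' @param gel,sa,mc Mass fractions in wt%, all >= 0.
#' @return A data frame of class `composition_ratio` with columns
#'   `Gel`, `SA`, `MC`.
#' @examples
#' composition_ratio(9, 4, 3)
#' @export
composition_ratio <- function(gel, sa, mc) {
  x <- data.frame(Gel = as.numeric(gel), SA = as.numeric(sa),
                  MC = as.numeric(mc))
  if (any(!is.finite(as.matrix(x))) || any(as.matrix(x) < 0))
    stop("composition fractions must be finite and >= 0")
  outside <- x$Gel < 6 | x$Gel > 10 | x$SA < 3 | x$SA > 5 | x$MC < 2 | x$MC > 4
  if (any(outside))
    warning(sum(outside), " composition(s) outside the design cube ",
            "Gel [6,10], SA [3,5], MC [2,4] wt%; predictions extrapolate")
  class(x) <- c("composition_ratio", "data.frame")
  x
}

as_composition <- function(ratio) {
  if (inherits(ratio, "composition_ratio")) return(ratio)
  if (is.data.frame(ratio) && all(c("Gel", "SA", "MC") %in% names(ratio)))
    return(composition_ratio(ratio$Gel, ratio$SA, ratio$MC))
  if (is.numeric(ratio) && length(ratio) == 3L)
    return(composition_ratio(ratio[1], ratio[2], ratio[3]))
  stop("ratio must be a composition_ratio, a data frame with Gel/SA/MC, ",
       "or a length-3 numeric vector")
}

# published response-surface coefficients for the power-law index (uncoded
# wt% units); only the terms retained by backward elimination are present
published_n_coefs <- c(
  "(Intercept)" = -0.256,
  "Gel" = 0.1638, "SA" = 0.1596, "MC" = 0.1828,
  "Gel^2" = -0.01107, "SA^2" = -0.0259, "MC^2" = -0.0213,
  "Gel:MC" = -0.01348
)

# published coefficients for the consistency coefficient; the raw polynomial
# evaluates in mPa.s (1000x the tabulated Pa.s values), hence output_scale 1e-3
published_K_coefs <- c(
  "(Intercept)" = 2014481,
  "Gel" = -277312, "SA" = -345128, "MC" = -329307,
  "Gel^2" = 10161, "SA^2" = 18857, "MC^2" = 19065,
  "Gel:SA" = 22029, "Gel:MC" = 21509, "SA:MC" = 22724
)

published_model <- function(coefs, response, output_scale = 1) {
  d <- bb_design_ink()
  structure(list(
    coefficients = coefs,
    term_mask = setdiff(names(coefs), "(Intercept)"),
    response = response,
    factors = d$factors,
    levels = d$levels,
    units = "uncoded",
    output_scale = output_scale,
    sigma = NA_real_,
    zero_variance = FALSE
  ), class = "quadratic_model")
}

#' Published composition-to-rheology response models
#'
#' The fitted second-order models mapping ink composition (wt%) to the
#' power-law index n and the consistency coefficient K (Pa.s). The K model's
#' raw polynomial evaluates in mPa.s, so an output scale factor of 1e-3 is
#' applied to report Pa.s; the factor was confirmed by evaluating the
#' polynomial at all five validation compositions against their tabulated
#' Pa.s values.
#'
#' @return A `quadratic_model` evaluable with [predict.quadratic_model()].
#' @export
ink_n_model <- function() published_model(published_n_coefs, "n")

#' @rdname ink_n_model
#' @export
ink_K_model <- function() published_model(published_K_coefs, "K", 1e-3)

#' Predict ink rheology from composition
#'
#' Evaluates the published response-surface polynomials at one or more
#' compositions. `predict_n()` returns the dimensionless power-law index,
#' `predict_K()` the consistency coefficient in Pa.s (unit scale already
#' resolved, see [ink_K_model()]).
#'
#' @param ratio A [composition_ratio()], a data frame with columns
#'   Gel/SA/MC, or a length-3 numeric vector (Gel, SA, MC in wt%).
#' @return Numeric vector of predictions.
#' @examples
#' predict_n(composition_ratio(9, 4, 3)) # ~0.54
#' predict_K(composition_ratio(9, 4, 3)) # ~93.05 Pa.s
#' @export
predict_n <- function(ratio) {
  predict(ink_n_model(), as_composition(ratio))
}

#' @rdname predict_n
#' @export
predict_K <- function(ratio) {
  predict(ink_K_model(), as_composition(ratio))
}

#' Prediction accuracy of a rheology model
#'
#' The accuracy convention used by the validation table:
#' `1 - |predicted - measured| / predicted`. Candidate denominators
#' (predicted vs measured) were brute-force checked against all published
#' accuracy cells; only the predicted-value denominator reproduces them.
#'
#' @param predicted Model prediction (> 0).
#' @param measured Measured value (> 0).
#' @return Accuracy as a fraction (1 = perfect agreement). Vectorized.
#' @export
prediction_accuracy <- function(predicted, measured) {
  if (any(!is.finite(measured)) || any(measured <= 0))
    stop("measured value must be finite and > 0")
  if (any(!is.finite(predicted)) || any(predicted <= 0))
    stop("predicted value must be finite and > 0")
  1 - abs(predicted - measured) / predicted
}

#' Enumerate the feasible rheology region over the composition cube
#'
#' Evaluates the published n and K models on a regular grid over the design
#' cube (Gel 6-10, SA 3-5, MC 2-4 wt%), giving the attainable (n, K) cloud.
#'
#' @param grid_steps Grid points per factor (>= 2; endpoints included).
#' @return Data frame with columns `Gel`, `SA`, `MC`, `n`, `K_pa_s`.
#' @export
enumerate_feasible_region <- function(grid_steps = 9L) {
  if (grid_steps < 2L) stop("grid_steps must be >= 2")
  g <- expand.grid(Gel = seq(6, 10, length.out = grid_steps),
                   SA = seq(3, 5, length.out = grid_steps),
                   MC = seq(2, 4, length.out = grid_steps))
  comp <- composition_ratio(g$Gel, g$SA, g$MC)
  data.frame(g, n = predict_n(comp), K_pa_s = predict_K(comp))
}

#' Read / write design-response CSV tables
#'
#' Columns `run, gel_wtpct, sa_wtpct, mc_wtpct, n, K_pa_s`.
#'
#' @param path File path.
#' @return A data frame with those columns.
#' @export
read_design_responses <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("run", "gel_wtpct", "sa_wtpct", "mc_wtpct", "n", "K_pa_s")
  if (!all(need %in% names(df)))
    stop("design-response CSV must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' @param table A data frame as returned by [read_design_responses()].
#' @rdname read_design_responses
#' @export
write_design_responses <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a fitted quadratic model to JSON
#'
#' Serializes coefficients, term mask, units, output scale and (when present)
#' diagnostics so a model can be archived next to run outputs.
#'
#' @param fit A `quadratic_fit` from [fit_quadratic()] or a `quadratic_model`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(fit, path) {
  model <- if (inherits(fit, "quadratic_fit")) fit$model else fit
  stopifnot(inherits(model, "quadratic_model"))
  out <- list(
    response = model$response,
    units = model$units,
    coefficients = as.list(model$coefficients),
    term_mask = model$term_mask,
    output_scale = model$output_scale
  )
  if (inherits(fit, "quadratic_fit")) {
    out$diagnostics <- list(
      r_squared = fit$anova$r_squared,
      adj_r_squared = fit$anova$adj_r_squared,
      pred_r_squared = fit$anova$pred_r_squared,
      press = fit$anova$press,
      lack_of_fit_p = fit$anova$lack_of_fit$p
    )
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
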