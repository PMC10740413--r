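#' Full second-order term set for a factor list
#'
#' Term labels are the factor names (linear), `f^2` (pure quadratic) and
#' `fi:fj` with i < j (two-way interactions).
#'
#' @param factors Character vector of factor names.
#' @return Character vector of the 3p(p+1)/2 / ... term labels
#'   (for 3 factors: 9 terms).
#' @export
quadratic_terms <- function(factors) {
  p <- length(factors)
  inter <- character(0)
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      inter <- c(inter, paste0(factors[i], ":", factors[j]))
  }
  c(factors, paste0(factors, "^2"), inter)
}

# evaluate polynomial term columns for a set of points (data frame of factors)
term_columns <- function(points, factors, terms) {
  points <- as.data.frame(points)
  cols <- lapply(terms, function(tm) {
    if (tm %in% factors) return(points[[tm]])
    if (grepl("\\^2$", tm)) {
      f <- sub("\\^2$", "", tm)
      return(points[[f]]^2)
    }
    fs <- strsplit(tm, ":", fixed = TRUE)[[1]]
    points[[fs[1]]] * points[[fs[2]]]
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

#' Fit a second-order response-surface model on a Box-Behnken design
#'
#' Ordinary least squares fit of the quadratic polynomial
#' \eqn{Y = \beta_0 + \sum\beta_i x_i + \sum\beta_{ii} x_i^2 +
#' \sum\beta_{ij} x_i x_j + \epsilon} with a configurable included-term mask,
#' together with the classical response-surface diagnostics: per-term partial
#' F tests, a lack-of-fit test partitioning pure error from the replicated
#' center runs, R-squared, adjusted R-squared, and predicted R-squared from
#' PRESS computed by the leave-one-out hat-value identity.
#'
#' By default the model is fitted on uncoded (natural wt%) units.
#'
#' @param design A [bb_design()].
#' @param responses Numeric vector, one response per design run.
#' @param term_mask Character vector of included term labels (subset of
#'   [quadratic_terms()] of the design factors). Default: all terms.
#' @param response_name Name of the response (annotation).
#' @param units `"uncoded"` (default) or `"coded"` regressor units.
#' @return A list of class `quadratic_fit` with elements `model`
#'   (class `quadratic_model`) and `anova` (class `rsm_anova`).
#' @export
fit_quadratic <- function(design, responses, term_mask = NULL,
                          response_name = "y",
                          units = c("uncoded", "coded")) {
  stopifnot(inherits(design, "bb_design"))
  units <- match.arg(units)
  n <- nrow(design$coded)
  if (length(responses) != n)
    stop("need exactly one response per design run")
  all_terms <- quadratic_terms(design$factors)
  if (is.null(term_mask)) term_mask <- all_terms
  if (!all(term_mask %in% all_terms))
    stop("unknown term(s) in mask: ",
         paste(setdiff(term_mask, all_terms), collapse = ", "))
  pts <- if (units == "coded") as.data.frame(design$coded) else design$uncoded
  X <- cbind(`(Intercept)` = 1, term_columns(pts, design$factors, term_mask))
  if (n < ncol(X))
    stop("insufficient runs: ", n, " runs for ", ncol(X), " coefficients")

  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular design for the requested term mask")
  beta <- qr.coef(qrX, responses)
  res <- drop(responses - X %*% beta)
  df_res <- n - ncol(X)
  sse <- sum(res^2)
  sst <- sum((responses - mean(responses))^2)
  sigma2 <- if (df_res > 0) sse / df_res else NA_real_

  XtX_inv <- chol2inv(chol(crossprod(X)))
  hat <- rowSums((X %*% XtX_inv) * X)
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)

  zero_var <- sst <= .Machine$double.eps * max(1, sum(responses^2))
  tval <- ifelse(se > 0, beta / se, 0)
  pval <- if (df_res > 0) 2 * stats::pt(-abs(tval), df_res) else rep(NA_real_, length(tval))
  if (zero_var) pval[] <- NA_real_

  # PRESS via the leave-one-out identity e_(i) = e_i / (1 - h_i)
  press <- sum((res / (1 - hat))^2)
  r2 <- if (zero_var) 0 else 1 - sse / sst
  adj_r2 <- if (zero_var || df_res == 0) NA_real_ else
    1 - (sse / df_res) / (sst / (n - 1))
  pred_r2 <- if (zero_var) 0 else 1 - press / sst

  # lack of fit: pure error from replicated design points (the center runs)
  key <- apply(design$coded, 1, paste, collapse = "/")
  grp <- split(responses, key)
  ss_pe <- sum(vapply(grp, function(y) sum((y - mean(y))^2), 0))
  df_pe <- sum(vapply(grp, length, 0L) - 1L)
  df_lof <- df_res - df_pe
  ss_lof <- max(sse - ss_pe, 0)
  lof <- if (df_lof > 0 && df_pe > 0 && ss_pe > 0) {
    Flof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    list(ss_lof = ss_lof, df_lof = df_lof, ss_pe = ss_pe, df_pe = df_pe,
         F = Flof, p = stats::pf(Flof, df_lof, df_pe, lower.tail = FALSE))
  } else {
    list(ss_lof = ss_lof, df_lof = df_lof, ss_pe = ss_pe, df_pe = df_pe,
         F = NA_real_, p = NA_real_)
  }

  # overall model F
  df_mod <- ncol(X) - 1L
  model_F <- if (!zero_var && df_res > 0)
    ((sst - sse) / df_mod) / (sse / df_res) else NA_real_
  model_p <- if (is.finite(model_F))
    stats::pf(model_F, df_mod, df_res, lower.tail = FALSE) else NA_real_

  terms_tab <- data.frame(
    term = colnames(X)[-1],
    coefficient = unname(beta[-1]),
    se = unname(se[-1]),
    effect = unname(tval[-1]),            # standardized effect (t value)
    ss = unname(tval[-1]^2) * sigma2,     # partial (type III) SS, 1 df each
    F = unname(tval[-1]^2),
    p = unname(pval[-1]),
    stringsAsFactors = FALSE
  )

  model <- structure(list(
    coefficients = beta,
    term_mask = term_mask,
    response = response_name,
    factors = design$factors,
    levels = design$levels,
    units = units,
    output_scale = 1,
    sigma = sqrt(sigma2),
    zero_variance = zero_var
  ), class = "quadratic_model")

  report <- structure(list(
    terms = terms_tab,
    model_F = model_F, model_p = model_p,
    lack_of_fit = lof,
    r_squared = r2, adj_r_squared = adj_r2,
    press = press, pred_r_squared = pred_r2,
    sse = sse, sst = sst, df_residual = df_res,
    n_runs = n, zero_variance = zero_var
  ), class = "rsm_anova")

  structure(list(model = model, anova = report), class = "quadratic_fit")
}

#' Evaluate a fitted (or published) quadratic model
#'
#' Pure polynomial evaluation of the stored coefficients at new composition
#' points, multiplied by the model's `output_scale`.
#'
#' @param object A `quadratic_model`.
#' @param newdata Data frame with one column per factor, natural (wt%) units.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!all(object$factors %in% names(newdata)))
    stop("newdata must contain columns: ",
         paste(object$factors, collapse = ", "))
  pts <- newdata[object$factors]
  if (object$units == "coded")
    pts <- as.data.frame(uncoded_to_coded(pts, object$levels))
  X <- cbind(1, term_columns(pts, object$factors, object$term_mask))
  drop(X %*% object$coefficients) * object$output_scale
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("Quadratic response model for '%s' (%s units, %d terms)\n",
              x$response, x$units, length(x$term_mask)))
  print(round(x$coefficients, 6))
  if (x$output_scale != 1)
    cat(sprintf("output scale: %g\n", x$output_scale))
  invisible(x)
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("R2 = %.4f, adj R2 = %.4f, pred R2 = %.4f (PRESS = %.4g)\n",
              x$r_squared, x$adj_r_squared, x$pred_r_squared, x$press))
  cat(sprintf("model F = %.3f (p = %.3g); lack-of-fit p = %.3g\n",
              x$model_F, x$model_p, x$lack_of_fit$p))
  print(x$terms[c("term", "coefficient", "effect", "p")], digits = 4)
  invisible(x)
}

# terms whose removal would break model hierarchy
protected_by_hierarchy <- function(term, mask, factors) {
  if (!(term %in% factors)) return(FALSE)
  higher <- setdiff(mask, factors)
  any(vapply(higher, function(h) {
    fs <- if (grepl("\\^2$", h)) sub("\\^2$", "", h) else
      strsplit(h, ":", fixed = TRUE)[[1]]
    term %in% fs
  }, FALSE))
}

#' Backward elimination with a predicted-R-squared retention rule
#'
#' Iteratively removes the highest-p term with p > `alpha`, unless removing it
#' would decrease the predicted R-squared, in which case the term is retained
#' permanently (this is how marginally non-significant pure-quadratic terms
#' can survive elimination when they help prediction). Model hierarchy is
#' respected: a linear term is never removed while any surviving higher-order
#' term contains it. The intercept is never removed.
#'
#' @inheritParams fit_quadratic
#' @param alpha Significance threshold for removal (default 0.05).
#' @return A `quadratic_fit` (see [fit_quadratic()]) with an extra element
#'   `removed`: the term labels eliminated, in order.
#' @export
backward_eliminate <- function(design, responses, term_mask = NULL,
                               alpha = 0.05, response_name = "y",
                               units = c("uncoded", "coded")) {
  units <- match.arg(units)
  if (is.null(term_mask)) term_mask <- quadratic_terms(design$factors)
  current <- fit_quadratic(design, responses, term_mask,
                           response_name = response_name, units = units)
  removed <- character(0)
  protected <- character(0)
  repeat {
    tab <- current$anova$terms
    mask <- current$model$term_mask
    cand <- tab[is.finite(tab$p) & tab$p > alpha &
                  !(tab$term %in% protected), , drop = FALSE]
    cand <- cand[!vapply(cand$term, protected_by_hierarchy, FALSE,
                         mask = mask, factors = design$factors), , drop = FALSE]
    if (nrow(cand) == 0) break
    worst <- cand$term[which.max(cand$p)]
    trial <- fit_quadratic(design, responses, setdiff(mask, worst),
                           response_name = response_name, units = units)
    if (trial$anova$pred_r_squared >= current$anova$pred_r_squared) {
      removed <- c(removed, worst)
      current <- trial
    } else {
      protected <- c(protected, worst)
    }
  }
  current$removed <- removed
  current
}

#' Terms ranked by absolute standardized effect (Pareto order)
#'
#' Orders the model terms by the absolute value of their standardized effect
#' (the t statistic of the partial test), descending; ties are broken
#' alphabetically by term label.
#'
#' @param report An `rsm_anova` report from [fit_quadratic()].
#' @return Data frame with columns `term` and `effect` (absolute standardized
#'   effect), in Pareto order.
#' @export
pareto_effects <- function(report) {
  stopifnot(inherits(report, "rsm_anova"))
  tab <- data.frame(term = report$terms$term,
                    effect = abs(report$terms$effect),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$effect, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
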