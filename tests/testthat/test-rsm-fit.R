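test_that("noise-free responses are recovered exactly", {
  d <- bb_design_ink()
  set.seed(11)
  truth <- setNames(runif(10, -2, 2), c("(Intercept)", quadratic_terms(d$factors)))
  X <- cbind(1, inkflow:::term_columns(d$uncoded, d$factors,
                                       quadratic_terms(d$factors)))
  y <- drop(X %*% truth)
  fit <- fit_quadratic(d, y)
  expect_equal(unname(fit$model$coefficients), unname(truth), tolerance = 1e-8)
  expect_equal(fit$anova$r_squared, 1, tolerance = 1e-10)
  expect_equal(predict(fit$model, d$uncoded), y, tolerance = 1e-8)
})

test_that("constant responses give a flagged zero R-squared", {
  d <- bb_design_ink()
  fit <- fit_quadratic(d, rep(3.5, 17))
  expect_true(fit$anova$zero_variance)
  expect_equal(fit$anova$r_squared, 0)
  expect_equal(max(abs(fit$model$coefficients[-1])), 0, tolerance = 1e-10)
  expect_equal(unname(fit$model$coefficients[1]), 3.5, tolerance = 1e-10)
})

test_that("PRESS equals an explicit leave-one-out refit loop", {
  d <- bb_design_ink()
  resp <- synth_bb_responses(d, 0.005, 2, seed = 21)
  fit <- fit_quadratic(d, resp$n)
  # explicit LOO: refit without each run, predict it, accumulate squared error
  X <- cbind(1, inkflow:::term_columns(d$uncoded, d$factors,
                                       quadratic_terms(d$factors)))
  press <- 0
  for (i in 1:17) {
    b <- qr.coef(qr(X[-i, ]), resp$n[-i])
    press <- press + (resp$n[i] - sum(X[i, ] * b))^2
  }
  expect_equal(fit$anova$press, press, tolerance = 1e-8)
  expect_gte(fit$anova$press, fit$anova$sse)
})

test_that("predicted R-squared never exceeds R-squared", {
  d <- bb_design_ink()
  for (s in 1:10) {
    resp <- synth_bb_responses(d, 0.01, 4, seed = 600 + s)
    for (y in list(resp$n, resp$K_pa_s)) {
      a <- fit_quadratic(d, y)$anova
      expect_lte(a$pred_r_squared, a$r_squared)
      expect_lte(a$adj_r_squared, a$r_squared)
      expect_gte(a$r_squared, 0)
      expect_lte(a$r_squared, 1)
    }
  }
})

test_that("coefficients fall within three standard errors of truth", {
  # per-coefficient coverage of a 3-SE window under t(7) residual df is ~98%;
  # assert a conservative 90% over 40 seeded replicates
  d <- bb_design_ink()
  truth_all <- setNames(rep(0, 9), quadratic_terms(d$factors))
  truth_all[names(eq_n_coefs)[-1]] <- eq_n_coefs[-1]
  mu <- predict(ink_n_model(), d$uncoded)
  inside <- 0L; total <- 0L
  for (s in 1:40) {
    set.seed(9000 + s)
    fit <- fit_quadratic(d, mu + rnorm(17, 0, 0.01))
    tab <- fit$anova$terms
    inside <- inside + sum(abs(tab$coefficient - truth_all[tab$term]) <=
                             3 * tab$se)
    total <- total + nrow(tab)
  }
  expect_gte(inside / total, 0.90)
})

test_that("lack-of-fit partitions pure error from the center replicates", {
  d <- bb_design_ink()
  resp <- synth_bb_responses(d, 0.01, 2, seed = 33)
  a <- fit_quadratic(d, resp$n)$anova
  expect_equal(a$lack_of_fit$df_pe, 4L)      # 5 center replicates
  expect_equal(a$lack_of_fit$df_lof, a$df_residual - 4L)
  expect_gte(a$lack_of_fit$p, 0)
  expect_lte(a$lack_of_fit$p, 1)
  expect_equal(a$lack_of_fit$ss_lof + a$lack_of_fit$ss_pe, a$sse,
               tolerance = 1e-10)
})

test_that("rank-deficient masks and bad inputs error", {
  d <- bb_design_ink()
  expect_error(fit_quadratic(d, 1:5), "one response per")
  expect_error(fit_quadratic(d, rnorm(17), term_mask = c("Gel", "bogus")),
               "unknown term")
})

test_that("backward elimination follows the p-value and retention rules", {
  d <- bb_design_ink()
  # data generated from the reduced structure: absent interactions are only
  # ever eliminated, and no true term is ever lost (retention rule keeps the
  # weak pure quadratics)
  true_terms <- names(eq_n_coefs)[-1]
  for (s in 1:20) {
    resp <- synth_bb_responses(d, 0.005, 2, seed = 5000 + s)
    be <- backward_eliminate(d, resp$n, alpha = 0.05, response_name = "n")
    expect_true(all(be$removed %in% c("Gel:SA", "SA:MC")))
    expect_true(all(true_terms %in% be$model$term_mask))
  }
})

test_that("backward elimination is a no-op when all terms are significant", {
  d <- bb_design_ink()
  set.seed(2)
  truth <- setNames(runif(10, 1, 3), c("(Intercept)", quadratic_terms(d$factors)))
  X <- cbind(1, inkflow:::term_columns(d$uncoded, d$factors,
                                       quadratic_terms(d$factors)))
  y <- drop(X %*% truth) + rnorm(17, 0, 1e-6)
  be <- backward_eliminate(d, y)
  expect_length(be$removed, 0)
  expect_setequal(be$model$term_mask, quadratic_terms(d$factors))
})

test_that("hierarchy keeps linear terms under surviving higher terms", {
  d <- bb_design_ink()
  # response depends only on Gel:MC -> Gel and MC linear terms must survive
  y <- 2 + 0.5 * d$uncoded$Gel * d$uncoded$MC
  set.seed(3); y <- y + rnorm(17, 0, 1e-3)
  be <- backward_eliminate(d, y)
  expect_true("Gel:MC" %in% be$model$term_mask)
  expect_true(all(c("Gel", "MC") %in% be$model$term_mask))
})

test_that("Pareto ordering ranks terms by absolute standardized effect", {
  d <- bb_design_ink()
  resp <- synth_bb_responses(d, 0.002, 1, seed = 77)
  # standardized effects are compared in coded units (as response-surface
  # software does); data simulated from the published n model reproduce its
  # reported effect ordering
  pe <- pareto_effects(fit_quadratic(d, resp$n, units = "coded")$anova)
  expect_equal(pe$term[1:7], c("Gel", "MC", "SA", "Gel^2", "Gel:MC",
                               "SA^2", "MC^2"))
  expect_true(all(diff(pe$effect) <= 0))
  # tie-break: equal effects ordered alphabetically
  fake <- structure(list(terms = data.frame(
    term = c("Zeta", "Alpha"), coefficient = c(1, 1), se = c(1, 1),
    effect = c(2, 2), ss = c(1, 1), F = c(4, 4), p = c(0.1, 0.1))),
    class = "rsm_anova")
  expect_equal(pareto_effects(fake)$term, c("Alpha", "Zeta"))
  single <- structure(list(terms = data.frame(
    term = "Gel", coefficient = 1, se = 1, effect = 5, ss = 1, F = 25,
    p = 0.01)), class = "rsm_anova")
  expect_equal(pareto_effects(single)$term, "Gel")
})
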