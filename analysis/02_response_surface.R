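#!/usr/bin/env Rscript
# Stage 2 — composition-to-rheology response-surface models.
#
# Builds the 17-run Box-Behnken design (5 center replicates) over
# Gel 6-10 / SA 3-5 / MC 2-4 wt%, fits second-order models for the power-law
# index and consistency coefficient on synthetic responses, reduces them by
# backward elimination with the predicted-R2 retention rule, and tabulates
# the published-model predictions at the five validation compositions plus
# the feasible (n, K) region over the composition cube.

library(inkflow)

dir.create("results", showWarnings = FALSE)
design <- bb_design_ink()
responses <- synth_bb_responses(design, sigma_n = 0.005, sigma_K = 2,
                                seed = 202)
write_design_responses(responses, "results/02_design_responses.csv")

fit_n <- backward_eliminate(design, responses$n, response_name = "n")
fit_K <- backward_eliminate(design, responses$K_pa_s, response_name = "K")
write_model_json(fit_n, "results/02_model_n.json")
write_model_json(fit_K, "results/02_model_K.json")

cat("Reduced n model:", length(fit_n$model$term_mask), "terms; removed:",
    paste(fit_n$removed, collapse = ", "), "\n")
cat(sprintf("  R2 %.4f, adj %.4f, predicted %.4f; lack-of-fit p = %.2f\n",
            fit_n$anova$r_squared, fit_n$anova$adj_r_squared,
            fit_n$anova$pred_r_squared, fit_n$anova$lack_of_fit$p))
cat("Pareto order (coded units):\n")
print(pareto_effects(fit_quadratic(design, responses$n,
                                   units = "coded")$anova),
      row.names = FALSE, digits = 3)

val <- composition_ratio(c(10, 6, 7, 7.5, 9), c(4, 5, 4, 3, 5),
                         c(3, 4, 4, 2, 3))
pred <- data.frame(val, n_pred = round(predict_n(val), 2),
                   K_pred_pa_s = round(predict_K(val), 2))
write.csv(pred, "results/02_predictions.csv", row.names = FALSE)
cat("\nPublished-model predictions at the validation compositions:\n")
print(pred, row.names = FALSE)

region <- enumerate_feasible_region(9L)
write.csv(region, "results/02_feasible_region.csv", row.names = FALSE)
cat(sprintf("\nFeasible region over the cube: n in [%.2f, %.2f], K in [%.1f, %.1f] Pa.s\n",
            min(region$n), max(region$n),
            min(region$K_pa_s), max(region$K_pa_s)))
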