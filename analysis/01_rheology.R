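#!/usr/bin/env Rscript
# Stage 1 — shear-thinning rheology of the ink family.
#
# Generates synthetic 21-point flow curves (1-100 1/s, log-uniform) for the
# low-, mid- and high-viscosity reference inks (7:4:3, 8:4:3, 9:4:3), fits
# the power-law model in log-log space, and reports how well (n, K) are
# recovered under multiplicative measurement noise.

library(inkflow)

dir.create("results", showWarnings = FALSE)
refs <- data.frame(Gel = c(7, 8, 9), SA = 4, MC = 3)

rows <- do.call(rbind, lapply(seq_len(nrow(refs)), function(i) {
  curve <- synth_rheometry(refs[i, ], synth_config(seed = 100 + i,
                                                   sigma_log = 0.03))
  fit <- fit_power_law(curve)
  truth <- attr(curve, "truth")
  data.frame(refs[i, ], n_true = truth$n, K_true = truth$K,
             n_fit = fit$params$n, K_fit = fit$params$K,
             r_squared = fit$r_squared)
}))
write.csv(rows, "results/01_rheology_fits.csv", row.names = FALSE)

cat("Power-law fits on synthetic rheometry (sigma_log = 0.03):\n")
print(rows, row.names = FALSE, digits = 4)
cat(sprintf(
  "\nMax recovery error: n %.4f, K %.2f%% relative; log-log R^2 >= %.4f\n",
  max(abs(rows$n_fit - rows$n_true)),
  100 * max(abs(rows$K_fit / rows$K_true - 1)),
  min(rows$r_squared)))
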