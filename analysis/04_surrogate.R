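#!/usr/bin/env Rscript
# Stage 4 — sampled surrogate of the flow-rate surface.
#
# Latin-hypercube samples the printable box (n 0.45-0.7, K 10-100 Pa.s,
# P 50-350 kPa) with 300 training points, solves each with the nozzle model,
# trains the feed-forward surrogate, scores it on 50 fresh random points
# (MAE/RMSE as % of the observed flow-rate range), and partitions the
# 250 kPa viscosity surface into three printability regimes by k-means.

library(inkflow)

dir.create("results", showWarnings = FALSE)
seed <- 404L

ds <- synth_flow_dataset(300, 50, seed = seed)
write_flow_dataset(ds$train, "results/04_flow_train.csv")
write_flow_dataset(ds$test, "results/04_flow_test.csv")
cat(sprintf("Solved 350 samples; training Q spans %.3g-%.3g uL/s (median %.3g)\n",
            min(ds$train$Q_ul_s), max(ds$train$Q_ul_s),
            median(ds$train$Q_ul_s)))

model <- train_surrogate(ds$train, seed = seed)
write_surrogate_json(model, "results/04_surrogate.json")
err <- evaluate_surrogate(model, ds$test, ds$test$Q_ul_s)
print(err)
jsonlite::write_json(
  list(mae_ul_s = err$mae, rmse_ul_s = err$rmse,
       mae_pct_of_range = err$mae_pct, rmse_pct_of_range = err$rmse_pct,
       n_test = err$n_test),
  "results/04_surrogate_errors.json", auto_unbox = TRUE, digits = NA)

surface <- flow_surface(250, grid_steps = 15)
regimes <- classify_regimes(surface, seed = seed)
write.csv(regimes, "results/04_regimes_250kPa.csv", row.names = FALSE)
cat("\nViscosity regimes at 250 kPa (ordered by mean flow rate):\n")
print(attr(regimes, "regimes"), row.names = FALSE, digits = 3)
cat("Flow in the high-viscosity regime varies least, so printing settings\n",
    "transfer best between inks in that region.\n")
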