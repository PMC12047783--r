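#!/usr/bin/env Rscript
# Iterated 3-fold cross-validated comparison of the full model against the
# reduced variants on synthetic training-group observers. Desk-scale
# settings (5 iterations, small optimizer budgets); the full-scale setting
# is 34 iterations (102 fold-evaluations).

suppressPackageStartupMessages(library(perclearn))

trials <- read_trials("results/study_trials.csv")
seed <- 11L
spec <- loss_spec(trial_budget = 150, grid_step = 2)

ids <- head(unique(trials$observer_id[trials$group == "est_train"]), 2)
summaries <- list()
for (id in ids) {
  message("Cross-validating ", id,
          " (full vs no_GC vs no_BA vs no_CI; k=3, 5 iterations) ...")
  t0 <- Sys.time()
  cv <- cross_validate_models(trials[trials$observer_id == id, ],
                              variants = c("full", "no_GC", "no_BA", "no_CI"),
                              k = 3, iterations = 5, spec = spec,
                              n_restarts = 2, budget = 100, seed = seed)
  message(sprintf("  done in %.0f s", as.numeric(Sys.time() - t0,
                                                 units = "secs")))
  print(cv$summary)
  summaries[[id]] <- cbind(observer = id, cv$summary)
}
all_sum <- do.call(rbind, summaries)
write.csv(all_sum, "results/cv_summary.csv", row.names = FALSE)

agg <- aggregate(cbind(train_loss, test_loss, delta_test) ~ variant,
                 data = all_sum, FUN = mean)
message("Mean CV loss across observers (delta_test is relative to the full model):")
print(agg)
message("Wrote results/cv_summary.csv")
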