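#!/usr/bin/env Rscript
# Fit the full observer model to individual synthetic observers and compare
# the fitted model's behavior with the (known) generating behavior.
# Desk-scale optimizer settings; see the methods vignette for the scaling.

suppressPackageStartupMessages(library(perclearn))

trials <- read_trials("results/study_trials.csv")
truth <- read_ground_truth("results/ground_truth.json")
seed <- 7L

fit_ids <- head(unique(trials$observer_id[trials$group == "est_train"]), 3)
spec <- loss_spec(trial_budget = 300, grid_step = 1)

fits <- list()
for (id in fit_ids) {
  message("Fitting ", id, " (full model, 6 restarts x 300 evaluations) ...")
  t0 <- Sys.time()
  f <- fit_observer(trials[trials$observer_id == id, ],
                    make_variant("full"), spec,
                    n_restarts = 6, budget = 300, seed = seed)
  message(sprintf("  best loss %.3f in %.0f s (restarts: %s)",
                  f$best_loss, as.numeric(Sys.time() - t0, units = "secs"),
                  paste(signif(f$restart_losses, 3), collapse = ", ")))
  tp <- truth[[id]]$params
  bp <- f$best_params
  message(sprintf("  gain change: true %.1f -> %.1f, fitted %.1f -> %.1f",
                  tp$g_pre, tp$g_post, bp$g_pre, bp$g_post))
  fits[[id]] <- list(observer = id, best_loss = f$best_loss,
                     restart_losses = f$restart_losses,
                     weights = as.list(f$weights),
                     fitted = list(a = bp$warp$a, w_b = bp$warp$w_b,
                                   sigma_b = bp$warp$sigma_b,
                                   g_pre = bp$g_pre, g_post = bp$g_post,
                                   lambda = bp$lambda),
                     truth = tp, seed = seed)
}
jsonlite::write_json(fits, "results/fits.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("Wrote results/fits.json")
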