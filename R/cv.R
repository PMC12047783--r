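#' Iterated stratified k-fold cross-validated model comparison
#'
#' For each iteration, one observer's trials are partitioned into k folds,
#' stratified by session x task x stimulus; each variant is fitted on the
#' training trials and its loss evaluated on the held-out fold. The loss
#' weights are computed once for the observer (full data, initial parameter
#' set) and held fixed across variants, folds and iterations, so train and
#' test losses live in the same space for every model.
#'
#' @param data One observer's trial table.
#' @param variants Character vector of variant names (must include "full"
#'   for the deltas) or a list of [make_variant()] objects.
#' @param k Folds (default 3).
#' @param iterations Repartition count (default 5 for desk-scale work; the
#'   full-scale setting is 34, i.e. 102 fold-evaluations).
#' @param spec A [loss_spec()].
#' @param n_restarts,budget Optimizer settings per fit (see [fit_observer()]).
#' @param seed Optional RNG seed.
#' @param shared A [shared_params()] used when variant names are given.
#' @return An object of class `cv_result`: list with `folds` (long
#'   data.frame: variant, iteration, fold, train_loss, test_loss), `summary`
#'   (per-variant mean train/test loss and `delta_test` vs the full model),
#'   and `weights`.
#' @export
cross_validate_models <- function(data, variants = c("full", "no_GC", "no_BA",
                                                     "no_CI", "TC"),
                                  k = 3, iterations = 5, spec = loss_spec(),
                                  n_restarts = 3, budget = 150, seed = NULL,
                                  shared = shared_params()) {
  check_trials(data)
  stopifnot(k >= 2, iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(variants))
    variants <- lapply(variants, make_variant, shared = shared)
  names(variants) <- vapply(variants, `[[`, character(1), "name")

  strata <- interaction(data$session, data$task, data$stimulus_deg, drop = TRUE)
  small <- table(strata) < k
  if (any(small))
    stop("stratum smaller than k: ", paste(names(which(small)), collapse = ", "))

  weights <- compute_loss_weights(data, variants[[1]], spec)

  rows <- list()
  for (it in seq_len(iterations)) {
    fold_id <- integer(nrow(data))
    for (s in levels(strata)) {
      idx <- which(strata == s)
      fold_id[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    for (f in seq_len(k)) {
      train <- data[fold_id != f, ]
      test <- observer_condition_data(data[fold_id == f, ])
      for (v in variants) {
        fit <- fit_observer(train, v, spec, n_restarts = n_restarts,
                            budget = budget, weights = weights)
        test_loss <- as.numeric(behavioral_loss(test, fit$best_theta, v, spec,
                                                weights = weights))
        rows[[length(rows) + 1L]] <-
          data.frame(variant = v$name, iteration = it, fold = f,
                     train_loss = fit$best_loss, test_loss = test_loss)
      }
    }
  }
  folds <- do.call(rbind, rows)
  summ <- stats::aggregate(cbind(train_loss, test_loss) ~ variant,
                           data = folds, FUN = mean)
  if ("full" %in% summ$variant) {
    full_test <- summ$test_loss[summ$variant == "full"]
    summ$delta_test <- summ$test_loss - full_test
  }
  structure(list(folds = folds, summary = summ, weights = weights,
                 k = k, iterations = iterations, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> k=%d, iterations=%d (%d fold-evaluations/variant)\n",
              x$k, x$iterations, x$k * x$iterations))
  print(x$summary)
  invisible(x)
}
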