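#' Bounded (1,lambda) evolution strategy for noisy objectives
#'
#' Minimizes a stochastic objective over a box by a simple evolution
#' strategy: each generation draws `lambda_offspring` Gaussian perturbations
#' of the incumbent (in normalized coordinates, clipped to the box),
#' re-evaluates the incumbent (so Monte-Carlo noise cannot freeze it on a
#' lucky draw), moves to the best offspring if it beats the incumbent's fresh
#' value, and adapts the step size up on success, down on failure. The
#' evaluation budget is fixed; derivative-free throughout.
#'
#' @param fn Objective `function(x)` returning a scalar (may be stochastic).
#' @param lower,upper Box bounds.
#' @param budget Total number of `fn` evaluations (default 300).
#' @param lambda_offspring Offspring per generation (default 8).
#' @param sigma0 Initial step size in normalized coordinates (default 0.3).
#' @param x0 Optional start point (default: uniform draw in the box).
#' @return A list with `par`, `value` (the incumbent's last evaluation),
#'   `n_eval`, and `sigma_final`.
#' @export
es_minimize <- function(fn, lower, upper, budget = 300, lambda_offspring = 8,
                        sigma0 = 0.3, x0 = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), budget >= lambda_offspring + 2)
  span <- upper - lower
  to_unit <- function(x) ifelse(span > 0, (x - lower) / span, 0.5)
  from_unit <- function(u) lower + u * span
  u <- if (is.null(x0)) stats::runif(d) else to_unit(x0)
  f_inc <- fn(from_unit(u))
  n_eval <- 1L
  sigma <- sigma0
  while (n_eval + lambda_offspring + 1L <= budget) {
    off <- matrix(stats::rnorm(lambda_offspring * d, 0, sigma),
                  lambda_offspring, d)
    off <- sweep(off, 2, u, "+")
    off <- pmin(pmax(off, 0), 1)
    f_off <- apply(off, 1, function(r) fn(from_unit(r)))
    f_inc <- fn(from_unit(u))  # fresh evaluation of the incumbent
    n_eval <- n_eval + lambda_offspring + 1L
    j <- which.min(f_off)
    if (f_off[j] < f_inc) {
      u <- off[j, ]
      f_inc <- f_off[j]
      sigma <- min(sigma * 1.25, 0.5)
    } else {
      sigma <- max(sigma * 0.8, 0.02)
    }
  }
  list(par = from_unit(u), value = f_inc, n_eval = n_eval,
       sigma_final = sigma)
}

#' Fit the observer model to one observer's data
#'
#' Minimizes [behavioral_loss()] over the variant's free parameters with
#' [es_minimize()], restarted from independent random points; the restart
#' with the lowest final loss wins.
#'
#' @param data One observer's trial table or an [observer_condition_data()]
#'   summary.
#' @param variant A [make_variant()] object.
#' @param spec A [loss_spec()].
#' @param n_restarts Number of optimizer restarts (default 10).
#' @param budget Objective evaluations per restart (default 300).
#' @param weights Loss weights `c(w_disc, w_est)`; computed via
#'   [compute_loss_weights()] when `NULL`.
#' @param seed Optional RNG seed (controls restarts, simulations, weights).
#' @return An object of class `fit_result`: list with `best_params`
#'   ([observer_params()]), `best_theta`, `best_loss`, `restart_losses`,
#'   `weights`, `variant`, `seed`.
#' @export
fit_observer <- function(data, variant = make_variant("full"),
                         spec = loss_spec(), n_restarts = 10, budget = 300,
                         weights = NULL, seed = NULL) {
  stopifnot(n_restarts >= 1)
  if (is.data.frame(data)) data <- observer_condition_data(data)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) weights <- compute_loss_weights(data, variant, spec)
  obj <- function(theta) as.numeric(
    behavioral_loss(data, theta, variant, spec, weights = weights))
  thetas <- vector("list", n_restarts)
  losses <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    res <- es_minimize(obj, variant$lower, variant$upper, budget = budget)
    thetas[[r]] <- res$par
    losses[r] <- res$value
  }
  best <- which.min(losses)
  structure(list(best_params = variant$theta_to_params(thetas[[best]]),
                 best_theta = thetas[[best]], best_loss = losses[best],
                 restart_losses = losses, weights = weights,
                 variant = variant$name, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> variant=%s best_loss=%.4g (restarts: %s)\n",
              x$variant, x$best_loss,
              paste(signif(x$restart_losses, 3), collapse = ", ")))
  print(x$best_params)
  invisible(x)
}
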