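#' Loss specification for model fitting
#'
#' @param trial_budget Simulated trials per stimulus x session in each loss
#'   evaluation (default 1500, the full-scale Monte-Carlo budget; reduce for
#'   desk-scale work).
#' @param grid_step Direction-grid step used during fitting, degrees
#'   (default 0.5).
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(trial_budget = 1500, grid_step = 0.5) {
  stopifnot(trial_budget >= 100, grid_step > 0)
  structure(list(trial_budget = trial_budget, grid_step = grid_step),
            class = "loss_spec")
}

#' Condition-level data summary for one observer
#'
#' Collapses one observer's trials and extracts, for each session x (collapsed)
#' stimulus condition, the discrimination accuracy and the estimate sample --
#' the two sides of the fitting loss. Errors if a required condition is
#' absent.
#'
#' @param trials One observer's trial table (both sessions, both tasks).
#' @param stimuli Collapsed stimulus magnitudes expected (default 2, 4, 8).
#' @return A list with `stimuli`, `disc_acc` (2 x k matrix, rows pre/post),
#'   and `est` (nested list `est[[session]][[as.character(stim)]]`).
#' @export
observer_condition_data <- function(trials, stimuli = c(2, 4, 8)) {
  check_trials(trials)
  coll <- collapse_by_category(trials)
  sessions <- c("pre", "post")
  disc_acc <- matrix(NA_real_, 2, length(stimuli),
                     dimnames = list(sessions, stimuli))
  est <- list(pre = list(), post = list())
  for (ss in sessions) for (st in stimuli) {
    d <- coll[coll$session == ss & coll$task == "disc" &
                coll$stimulus_deg == st, ]
    e <- coll[coll$session == ss & coll$task == "est" &
                coll$stimulus_deg == st, ]
    if (nrow(d) == 0)
      stop(sprintf("missing condition: session=%s task=disc stimulus=%g", ss, st))
    if (nrow(e) == 0)
      stop(sprintf("missing condition: session=%s task=est stimulus=%g", ss, st))
    disc_acc[ss, as.character(st)] <- mean(d$response == d$category)
    est[[ss]][[as.character(st)]] <- as.numeric(e$response)
  }
  list(stimuli = stimuli, disc_acc = disc_acc, est = est)
}

# Model-side condition summary for a parameter vector under a variant: one
# estimation-task simulation per session x stimulus provides both the lapsed
# implicit-discrimination accuracy and the estimate sample.
simulate_condition_summary <- function(theta, variant, spec, stimuli = c(2, 4, 8)) {
  grid <- direction_grid(spec$grid_step)
  prm <- variant$theta_to_params(theta)
  out <- list(stimuli = stimuli,
              disc_acc = matrix(NA_real_, 2, length(stimuli),
                                dimnames = list(c("pre", "post"), stimuli)),
              est = list(pre = list(), post = list()))
  for (ss in c("pre", "post")) {
    pop <- variant$make_pop(theta, ss, grid)
    for (j in seq_along(stimuli)) {
      st <- stimuli[j]
      sim <- sim_stimulus(pop, st, spec$trial_budget, "est",
                          conditional = variant$conditional,
                          sigma_m = prm$shared$sigma_m)
      out$disc_acc[ss, j] <- apply_lapse(mean(sim$choice == "CW"), prm$lambda)
      out$est[[ss]][[as.character(st)]] <- sim$est
    }
  }
  out
}

#' Behavioral loss: weighted L1 accuracy difference + energy distance
#'
#' The fit objective for one observer: the L1 difference between data and
#' model discrimination accuracy, summed over the three collapsed stimuli and
#' the two sessions, plus the energy distance between data and model estimate
#' distributions, summed the same way; each term multiplied by its weight.
#' Stochastic: the model side is a fresh Monte-Carlo simulation (seed the RNG
#' for bit-identical evaluations).
#'
#' @param data An [observer_condition_data()] summary (or a raw trial table,
#'   converted internally).
#' @param theta Free-parameter vector of the variant (or an
#'   [observer_params()] for the full model).
#' @param variant A [make_variant()] object (default full model).
#' @param spec A [loss_spec()].
#' @param weights `c(w_disc, w_est)` loss weights (default both 1; see
#'   [compute_loss_weights()]).
#' @param seed Optional RNG seed for the model simulation.
#' @return The scalar loss, with attribute `terms = c(l1, energy)` (the
#'   unweighted terms).
#' @export
behavioral_loss <- function(data, theta, variant = make_variant("full"),
                            spec = loss_spec(), weights = c(1, 1),
                            seed = NULL) {
  if (is.data.frame(data)) data <- observer_condition_data(data)
  if (inherits(theta, "observer_params")) theta <- variant$params_to_theta(theta)
  stopifnot(length(weights) == 2, all(weights >= 0))
  if (!is.null(seed)) set.seed(seed)
  mod <- simulate_condition_summary(theta, variant, spec, stimuli = data$stimuli)
  l1 <- sum(abs(data$disc_acc - mod$disc_acc))
  en <- 0
  for (ss in c("pre", "post")) for (st in as.character(data$stimuli))
    en <- en + energy_distance(data$est[[ss]][[st]], mod$est[[ss]][[st]])
  structure(weights[1] * l1 + weights[2] * en, terms = c(l1 = l1, energy = en))
}

#' Loss-term normalization weights
#'
#' Evaluates the two raw loss terms at an initial parameter vector (midpoint
#' of the variant's box bounds with a seeded 10 percent jitter unless given)
#' and returns reciprocal weights so both weighted terms start near 1. The
#' weights are computed once per observer and then held fixed across model
#' variants and cross-validation folds.
#'
#' @param data An [observer_condition_data()] summary or trial table.
#' @param variant A [make_variant()] object.
#' @param spec A [loss_spec()].
#' @param theta_init Optional explicit initial parameter vector.
#' @param seed Optional RNG seed (jitter + simulation).
#' @return `c(w_disc, w_est)`; a zero-valued term falls back to weight 1 with
#'   a warning.
#' @export
compute_loss_weights <- function(data, variant = make_variant("full"),
                                 spec = loss_spec(), theta_init = NULL,
                                 seed = NULL) {
  if (is.data.frame(data)) data <- observer_condition_data(data)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta_init)) {
    mid <- (variant$lower + variant$upper) / 2
    jit <- 1 + 0.1 * stats::runif(length(mid), -1, 1)
    theta_init <- pmin(pmax(mid * jit, variant$lower), variant$upper)
  }
  l <- behavioral_loss(data, theta_init, variant, spec, weights = c(1, 1))
  terms <- attr(l, "terms")
  w <- ifelse(terms > 0, 1 / terms, 1)
  if (any(terms == 0))
    warning("zero-valued loss term at theta_init; weight set to 1")
  stats::setNames(as.numeric(w), c("w_disc", "w_est"))
}
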