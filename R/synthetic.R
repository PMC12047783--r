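#' Study design for the synthetic three-group experiment
#'
#' @param groups Named integer vector: observers per group.
#' @param stimuli Tested directions, degrees.
#' @param trials_per_direction Estimation (and discrimination) trials per
#'   direction per session (default 60: 360-trial blocks over 6 directions).
#' @param grid_step Simulation grid step, degrees.
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = c(control = 7, disc_train = 7, est_train = 7),
                         stimuli = c(-8, -4, -2, 2, 4, 8),
                         trials_per_direction = 60, grid_step = 0.5) {
  stopifnot(all(groups >= 1), trials_per_direction >= 1,
            all(sort(unique(abs(stimuli))) == sort(unique(abs(-stimuli)))))
  structure(list(groups = groups, stimuli = stimuli,
                 trials_per_direction = trials_per_direction,
                 grid_step = grid_step),
            class = "study_design")
}

#' Draw generative observer parameters for one synthetic observer
#'
#' Parameters are drawn from documented ranges spanning the regimes the model
#' exhibits, from near-unbiased to highly biased observers: warp amplitude
#' `a` in \[2, 12\], boundary width `w_b` in \[10, 30\] deg, edge softness
#' `sigma_b` in \[1, 6\] deg, pre-training gain `g_pre` in \[3, 8\],
#' lapse in \[0, 0.1\], motor noise SD in \[1, 4\] deg. Training groups (or
#' `learning_effect = "gain"`) draw `g_post/g_pre` in \[1.5, 3\]; the control
#' group gets `g_post = g_pre` exactly.
#'
#' @param group One of "control", "disc_train", "est_train".
#' @param learning_effect "none" or "gain"; defaults to "gain" for training
#'   groups and "none" for control.
#' @param seed Optional RNG seed (draws are bit-reproducible given a seed).
#' @param shared A [shared_params()] template; its `sigma_m` is replaced by
#'   the per-observer draw.
#' @return An [observer_params()] object.
#' @export
sample_observer_params <- function(group = c("control", "disc_train", "est_train"),
                                   learning_effect = NULL, seed = NULL,
                                   shared = shared_params()) {
  group <- match.arg(group)
  if (is.null(learning_effect))
    learning_effect <- if (group == "control") "none" else "gain"
  learning_effect <- match.arg(learning_effect, c("none", "gain"))
  if (!is.null(seed)) set.seed(seed)
  a <- stats::runif(1, 2, 12)
  w_b <- stats::runif(1, 10, 30)
  sigma_b <- stats::runif(1, 1, 6)
  g_pre <- stats::runif(1, 3, 8)
  lambda <- stats::runif(1, 0, 0.1)
  sigma_m <- stats::runif(1, 1, 4)
  ratio <- if (learning_effect == "gain") stats::runif(1, 1.5, 3) else 1
  sh <- shared_params(n = shared$n, w_t = shared$w_t, b = shared$b,
                      sigma_m = sigma_m, sigma_g = shared$sigma_g)
  observer_params(warp_spec(a, w_b, sigma_b), g_pre = g_pre,
                  g_post = ratio * g_pre, lambda = lambda, shared = sh)
}

#' Generate a full synthetic study
#'
#' Simulates every observer of the three-group pre/post design through the
#' mechanistic observer model: both sessions, both tasks, all directions.
#' Discrimination responses additionally express the observer's lapse at the
#' trial level (a correct model response is flipped with probability lambda,
#' so expected accuracy matches the aggregate lapse rule).
#'
#' @param design A [study_design()].
#' @param seed RNG seed; the whole table is bit-reproducible given the seed.
#' @return A trial table (data.frame, one row per trial, schema as in
#'   [read_trials()]) with attribute `ground_truth`: a named list per
#'   observer with the generating parameters and sub-seed.
#' @export
generate_study <- function(design = study_design(), seed = 1) {
  stopifnot(inherits(design, "study_design"))
  groups <- rep(names(design$groups), design$groups)
  n_obs <- length(groups)
  obs_ids <- sprintf("O%02d", seq_len(n_obs))
  truth <- list()
  out <- vector("list", n_obs)
  for (i in seq_len(n_obs)) {
    obs_seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    prm <- sample_observer_params(groups[i], seed = obs_seed)
    truth[[obs_ids[i]]] <- list(group = groups[i], seed = obs_seed,
                                params = params_to_list(prm))
    blocks <- list()
    for (ss in c("pre", "post")) for (tk in c("disc", "est")) {
      blk <- simulate_block(prm, ss, tk, stimuli = design$stimuli,
                            trials_per_stimulus = design$trials_per_direction,
                            grid_step = design$grid_step)
      tr <- blk$trials
      if (tk == "disc" && prm$lambda > 0) {
        correct <- tr$response == tr$category
        flip <- correct & stats::runif(nrow(tr)) < prm$lambda
        tr$response[flip] <- flip_label(tr$response[flip])
      }
      blocks[[paste(ss, tk)]] <- tr
    }
    tab <- do.call(rbind, blocks)
    tab$observer_id <- obs_ids[i]
    tab$group <- groups[i]
    tab$seed <- obs_seed
    tab$trial_index <- seq_len(nrow(tab))
    out[[i]] <- tab
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  trials <- trials[, c("observer_id", "group", "session", "task",
                       "stimulus_deg", "category", "response", "trial_index",
                       "seed")]
  attr(trials, "ground_truth") <- truth
  trials
}

#' Generate estimates from a two-component mixture
#'
#' A parametric stand-in for the observer model's bimodal estimate
#' distributions, used to unit-test the behavioral statistics in isolation:
#' a primary mode on the correct side of the boundary and a secondary
#' (misclassified) mode on the incorrect side.
#'
#' @param mu_pos Primary-mode mean, degrees (> 0).
#' @param mu_neg Secondary-mode mean, degrees (< 0).
#' @param sd Component SD(s), degrees (length 1 or 2).
#' @param w_neg Misclassification weight in \[0, 1\].
#' @param n Sample size.
#' @param seed Optional RNG seed.
#' @return Numeric sample of length `n`.
#' @export
generate_mixture_estimates <- function(mu_pos = 15, mu_neg = -9, sd = 3,
                                       w_neg = 0.25, n = 100, seed = NULL) {
  stopifnot(mu_pos > 0, mu_neg < 0, w_neg >= 0, w_neg <= 1, n >= 1,
            all(sd > 0))
  if (length(sd) == 1) sd <- rep(sd, 2)
  if (!is.null(seed)) set.seed(seed)
  neg <- stats::runif(n) < w_neg
  ifelse(neg, stats::rnorm(n, mu_neg, sd[2]), stats::rnorm(n, mu_pos, sd[1]))
}

params_to_list <- function(p) {
  list(a = p$warp$a, w_b = p$warp$w_b, sigma_b = p$warp$sigma_b,
       g_pre = p$g_pre, g_post = p$g_post, lambda = p$lambda,
       n = p$shared$n, w_t = p$shared$w_t, b = p$shared$b,
       sigma_m = p$shared$sigma_m, sigma_g = p$shared$sigma_g)
}

params_from_list <- function(x) {
  observer_params(warp_spec(x$a, x$w_b, x$sigma_b), g_pre = x$g_pre,
                  g_post = x$g_post, lambda = x$lambda,
                  shared = shared_params(n = x$n, w_t = x$w_t, b = x$b,
                                         sigma_m = x$sigma_m,
                                         sigma_g = x$sigma_g))
}
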