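#' Draw task-generated stimuli (category prior 0.5/0.5)
#'
#' Mirrors the task's generative process: on each trial the category (CW vs
#' CCW of horizontal) is a fair coin flip, and the stimulus magnitude is drawn
#' uniformly from the tested directions.
#'
#' @param n_trials Number of trials.
#' @param magnitudes Stimulus magnitudes in degrees (default 2, 4, 8).
#' @param seed Optional RNG seed.
#' @return A data.frame with `category` ("CW"/"CCW") and `stimulus_deg`.
#' @export
sample_task_stimuli <- function(n_trials, magnitudes = c(2, 4, 8), seed = NULL) {
  stopifnot(n_trials >= 1, all(magnitudes > 0))
  if (!is.null(seed)) set.seed(seed)
  cw <- stats::runif(n_trials) < 0.5
  mag <- sample(magnitudes, n_trials, replace = TRUE)
  data.frame(category = ifelse(cw, "CW", "CCW"),
             stimulus_deg = ifelse(cw, mag, -mag))
}

#' Forward-simulate a block of trials for one observer and session
#'
#' Runs the full generative pipeline per trial: Poisson spiking from the
#' (possibly warped, possibly gain-elevated) encoding population, unaware
#' likelihood decoding, MAP discrimination, and -- for the estimation task --
#' the conditional (implicitly categorized) Bayes-least-squares estimate with
#' motor noise. The lapse acts on the aggregate accuracy in the summary, not
#' on individual trials.
#'
#' @param params An [observer_params()].
#' @param session "pre" or "post".
#' @param task "disc" or "est".
#' @param stimuli Stimulus directions in degrees (enumerated conditions;
#'   category is the stimulus sign). Default the six tested directions.
#' @param trials_per_stimulus Trials per direction (default 60; the study's
#'   per-session count. The model-evaluation Monte-Carlo budget default elsewhere is 1500).
#' @param seed Optional RNG seed; the block is bit-reproducible given a seed.
#' @param grid_step Direction-grid step, degrees.
#' @param conditional If `FALSE`, estimates are unconditional posterior means
#'   over the full domain (no-conditional-inference variant).
#' @param pop_override Optional prebuilt [build_population()] to use instead
#'   of building one from `params` (model variants).
#' @param task_prior If `TRUE`, stimuli are drawn by [sample_task_stimuli()]
#'   (`length(stimuli) * trials_per_stimulus` trials with magnitudes
#'   `abs(stimuli)`) instead of enumerated.
#' @return A list with `trials` (tidy per-trial data.frame: `trial_index`,
#'   `session`, `task`, `stimulus_deg`, `category`, `response`, `d`) and
#'   `summary` (per-stimulus data.frame: trial count, raw and lapsed
#'   p(Correct)). For the estimation task `response` is the estimate in
#'   degrees (as character); for discrimination it is "CW"/"CCW".
#' @export
simulate_block <- function(params, session = c("pre", "post"),
                           task = c("disc", "est"),
                           stimuli = c(-8, -4, -2, 2, 4, 8),
                           trials_per_stimulus = 60,
                           seed = NULL, grid_step = 0.1,
                           conditional = TRUE, pop_override = NULL,
                           task_prior = FALSE) {
  session <- match.arg(session)
  task <- match.arg(task)
  stopifnot(length(stimuli) >= 1, all(stimuli != 0), trials_per_stimulus >= 1)
  if (!is.null(seed)) set.seed(seed)

  pop <- if (is.null(pop_override)) {
    build_population(params, session, direction_grid(grid_step))
  } else pop_override
  if (task_prior) {
    drawn <- sample_task_stimuli(length(stimuli) * trials_per_stimulus,
                                 magnitudes = unique(abs(stimuli)))
    trial_stim <- drawn$stimulus_deg
  } else {
    trial_stim <- rep(stimuli, each = trials_per_stimulus)
  }

  us <- sort(unique(trial_stim))
  rows <- vector("list", length(us))
  sum_rows <- vector("list", length(us))
  for (k in seq_along(us)) {
    s0 <- us[k]
    n_t <- sum(trial_stim == s0)
    sim <- sim_stimulus(pop, s0, n_t, task, conditional = conditional,
                        sigma_m = params$shared$sigma_m)
    choice <- sim$choice
    d <- sim$d
    category <- if (s0 > 0) "CW" else "CCW"
    correct_raw <- mean(choice == category)
    response <- if (task == "est")
      formatC(sim$est, format = "g", digits = 17) else choice

    rows[[k]] <- data.frame(session = session, task = task,
                            stimulus_deg = s0, category = category,
                            response = response, d = d)
    sum_rows[[k]] <- data.frame(session = session, task = task,
                                stimulus_deg = s0, n = n_t,
                                p_correct_raw = correct_raw,
                                p_correct = apply_lapse(correct_raw,
                                                        params$lambda))
  }
  trials <- do.call(rbind, rows)
  trials$trial_index <- seq_len(nrow(trials))
  list(trials = trials, summary = do.call(rbind, sum_rows))
}
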