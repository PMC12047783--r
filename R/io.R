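trial_columns <- c("observer_id", "group", "session", "task", "stimulus_deg",
                   "category", "response", "trial_index", "seed")

check_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  need <- c("session", "task", "stimulus_deg", "category", "response")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  invisible(trials)
}

#' Read a trial table from CSV
#'
#' Validates the schema (all nine columns present, numeric stimulus, known
#' session/task/category levels, numeric estimation responses) and reports
#' offending rows by line number.
#'
#' @param path CSV file path.
#' @return A validated trial-table data.frame.
#' @export
read_trials <- function(path) {
  stopifnot(file.exists(path))
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(response = "character"))
  missing <- setdiff(trial_columns, names(tr))
  extra <- setdiff(names(tr), trial_columns)
  if (length(missing) || length(extra))
    stop("schema mismatch -- missing: [", paste(missing, collapse = ", "),
         "], extra: [", paste(extra, collapse = ", "), "]")
  bad <- which(!is.finite(suppressWarnings(as.numeric(tr$stimulus_deg))))
  if (length(bad))
    stop("non-numeric stimulus_deg on data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  tr$stimulus_deg <- as.numeric(tr$stimulus_deg)
  bad_lvl <- which(!(tr$session %in% c("pre", "post")) |
                     !(tr$task %in% c("disc", "est")) |
                     !(tr$category %in% c("CW", "CCW")))
  if (length(bad_lvl))
    stop("invalid session/task/category on data row(s): ",
         paste(utils::head(bad_lvl, 10), collapse = ", "))
  est <- tr$task == "est"
  has_resp <- !is.na(tr$response) & tr$response != "NA"
  bad_est <- which(est & has_resp &
                     !is.finite(suppressWarnings(as.numeric(tr$response))))
  if (length(bad_est))
    stop("non-numeric estimation response on data row(s): ",
         paste(utils::head(bad_est, 10), collapse = ", "))
  tr
}

#' Write a trial table to CSV
#'
#' @param trials A trial table.
#' @param path Output path (directories are created as needed).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trials[, trial_columns], path, row.names = FALSE)
  invisible(path)
}

#' Write / read the ground-truth sidecar of a generated study
#'
#' @param trials A [generate_study()] table (with `ground_truth` attribute).
#' @param path JSON path.
#' @return `path` (write) or the ground-truth list (read).
#' @export
write_ground_truth <- function(trials, path) {
  gt <- attr(trials, "ground_truth")
  stopifnot(!is.null(gt))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read / write a run configuration (JSON or YAML by extension)
#'
#' @param path Config path ending in .json, .yaml or .yml.
#' @param config Named list of settings.
#' @return The config list (read) or `path` (write).
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param n_perm Permutations for the statistics.
#' @param trial_budget,grid_step Loss-evaluation settings.
#' @param n_restarts,budget Optimizer settings.
#' @param cv_iterations,cv_k Cross-validation settings.
#' @param fit_observers How many observers to fit (0 skips fitting).
#' @param cv_variants Variant names compared by cross-validation (length < 2
#'   skips the comparison).
#' @param observers_per_group,trials_per_direction,sim_grid_step Study-design
#'   settings passed to [study_design()].
#' @return Named list.
#' @export
default_config <- function(seed = 1, out_dir = "results", n_perm = 200,
                           trial_budget = 300, grid_step = 1,
                           n_restarts = 2, budget = 120,
                           cv_iterations = 2, cv_k = 3, fit_observers = 1,
                           cv_variants = c("full", "no_GC"),
                           observers_per_group = 7,
                           trials_per_direction = 60, sim_grid_step = 0.5) {
  list(seed = seed, out_dir = out_dir, n_perm = n_perm,
       trial_budget = trial_budget, grid_step = grid_step,
       n_restarts = n_restarts, budget = budget,
       cv_iterations = cv_iterations, cv_k = cv_k,
       fit_observers = fit_observers, cv_variants = cv_variants,
       observers_per_group = observers_per_group,
       trials_per_direction = trials_per_direction,
       sim_grid_step = sim_grid_step)
}

#' Run the whole pipeline: simulate, analyse, fit, compare
#'
#' Desk-scale orchestration of the full workflow on a synthetic study:
#' generates the study, runs the behavioral statistics, fits the full model
#' to the first training-group observer(s), and cross-validates model
#' variants on the first of them. All outputs (CSV/JSON) are written under
#' `config$out_dir`, each stamped with the seed and config.
#'
#' @param config A [default_config()]-style list.
#' @return Invisibly, a list with the in-memory results (`trials`, `stats`,
#'   `fits`, `cv`) and the output paths.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(config$seed > 0)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  n_obs <- config$observers_per_group
  design <- study_design(
    groups = c(control = n_obs, disc_train = n_obs, est_train = n_obs),
    trials_per_direction = config$trials_per_direction,
    grid_step = config$sim_grid_step)
  trials <- generate_study(design, seed = config$seed)
  write_trials(trials, file.path(config$out_dir, "study_trials.csv"))
  write_ground_truth(trials, file.path(config$out_dir, "ground_truth.json"))

  stats_res <- summarize_study(trials, n_perm = config$n_perm,
                               seed = config$seed + 1)
  utils::write.csv(stats_res$accuracy,
                   file.path(config$out_dir, "accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_res$auroc, file.path(config$out_dir, "auroc.csv"),
                   row.names = FALSE)

  spec <- loss_spec(trial_budget = config$trial_budget,
                    grid_step = config$grid_step)
  train_obs <- unique(trials$observer_id[trials$group != "control"])
  fits <- list()
  ids <- utils::head(train_obs, config$fit_observers)
  for (id in ids) {
    fits[[id]] <- fit_observer(trials[trials$observer_id == id, ],
                               make_variant("full"), spec,
                               n_restarts = config$n_restarts,
                               budget = config$budget,
                               seed = config$seed + 2)
  }
  cv <- NULL
  if (length(ids) > 0 && length(config$cv_variants) > 1) {
    cv <- cross_validate_models(trials[trials$observer_id == ids[1], ],
                                variants = config$cv_variants,
                                k = config$cv_k,
                                iterations = config$cv_iterations,
                                spec = spec, n_restarts = config$n_restarts,
                                budget = config$budget,
                                seed = config$seed + 3)
    utils::write.csv(cv$summary,
                     file.path(config$out_dir, "cv_summary.csv"),
                     row.names = FALSE)
  }
  report <- list(config = config,
                 fits = lapply(fits, function(f)
                   list(variant = f$variant, best_loss = f$best_loss,
                        params = params_to_list(f$best_params))),
                 cv = if (!is.null(cv)) cv$summary)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(trials = trials, stats = stats_res, fits = fits, cv = cv,
                 out_dir = config$out_dir))
}
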