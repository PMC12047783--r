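#' Collapse trials across the boundary (merge up/down)
#'
#' Negates stimulus and response for downward (negative-direction) trials and
#' merges them with the upward trials, so that after collapsing every stimulus
#' is positive and a positive estimate lies on the correct-category side.
#' Discrimination responses are relabeled (CW <-> CCW) on flipped trials, so
#' correctness is preserved.
#'
#' @param trials A trial table (see [read_trials()] for the schema). Only the
#'   columns `stimulus_deg`, `category`, `task`, `response` are touched.
#' @return The collapsed trial table (class unchanged), with an added logical
#'   column `flipped`.
#' @export
collapse_by_category <- function(trials) {
  check_trials(trials)
  down <- trials$stimulus_deg < 0
  out <- trials
  out$stimulus_deg[down] <- -out$stimulus_deg[down]
  out$category[down] <- flip_label(out$category[down])
  est <- out$task == "est"
  fe <- down & est
  out$response[fe] <- formatC(-as.numeric(out$response[fe]),
                              format = "g", digits = 17)
  fd <- down & !est
  out$response[fd] <- flip_label(out$response[fd])
  out$flipped <- down
  out
}

flip_label <- function(x) ifelse(x == "CW", "CCW", ifelse(x == "CCW", "CW", x))

# Sign-flip map on the downward half; applying it twice is the identity.
flip_downward <- function(trials, which_rows = trials$stimulus_deg < 0) {
  out <- trials
  out$stimulus_deg[which_rows] <- -out$stimulus_deg[which_rows]
  out$category[which_rows] <- flip_label(out$category[which_rows])
  fe <- which_rows & out$task == "est"
  out$response[fe] <- formatC(-as.numeric(out$response[fe]),
                              format = "g", digits = 17)
  fd <- which_rows & out$task != "est"
  out$response[fd] <- flip_label(out$response[fd])
  out
}

# Numeric estimates from estimation-task rows.
est_values <- function(trials) as.numeric(trials$response[trials$task == "est"])

#' Per-cell discrimination and signed estimation accuracy
#'
#' Computes, for each observer x session x (collapsed) direction cell,
#' the discrimination accuracy (fraction of correct category reports) and the
#' signed estimation accuracy (fraction of estimates on the correct side of
#' the boundary; estimates exactly at 0 degrees belong to neither side and
#' are excluded from the numerator but kept in the denominator).
#'
#' @param trials A trial table; collapsed internally via
#'   [collapse_by_category()] if any stimulus is negative.
#' @return A data.frame with `observer_id`, `group`, `session`,
#'   `stimulus_deg`, `n_disc`, `disc_accuracy`, `n_est`, `signed_est_accuracy`.
#'   Cells with no trials get `NA`, not 0.
#' @export
accuracy_metrics <- function(trials) {
  check_trials(trials)
  if (any(trials$stimulus_deg < 0)) trials <- collapse_by_category(trials)
  cells <- unique(trials[, c("observer_id", "group", "session", "stimulus_deg")])
  cells <- cells[order(cells$observer_id, cells$session, cells$stimulus_deg), ]
  rownames(cells) <- NULL
  res <- cells
  res$n_disc <- res$disc_accuracy <- res$n_est <- res$signed_est_accuracy <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- trials$observer_id == cells$observer_id[i] &
      trials$session == cells$session[i] &
      trials$stimulus_deg == cells$stimulus_deg[i]
    d <- trials[sel & trials$task == "disc", ]
    e <- trials[sel & trials$task == "est", ]
    res$n_disc[i] <- nrow(d)
    if (nrow(d) > 0) res$disc_accuracy[i] <- mean(d$response == d$category)
    res$n_est[i] <- nrow(e)
    if (nrow(e) > 0) {
      est <- as.numeric(e$response)
      res$signed_est_accuracy[i] <- sum(est > 0) / length(est)
    }
  }
  res
}
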