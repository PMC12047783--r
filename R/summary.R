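#' Study-level summary tables
#'
#' Produces the descriptive tables the behavioral analyses are built on:
#' per-group accuracies pre/post, the per-observer x direction AUROC table
#' (permutation p-values and two-stage FDR flags), and the correlation
#' between signed estimation accuracy and discrimination accuracy across
#' observer x direction x session cells.
#'
#' @param trials A trial table covering both sessions and tasks.
#' @param n_perm Permutations for the AUROC tests (default 1000).
#' @param fdr_q FDR level for the AUROC table (default 0.05).
#' @param seed Optional RNG seed.
#' @return A list with `accuracy` (per-cell metrics), `group_accuracy`
#'   (group x session means), `auroc` (per observer x direction), and
#'   `accuracy_correlation` (Pearson r and the cells used; `NA` if either
#'   metric is constant).
#' @export
summarize_study <- function(trials, n_perm = 1000, fdr_q = 0.05, seed = NULL) {
  check_trials(trials)
  if (!is.null(seed)) set.seed(seed)
  coll <- collapse_by_category(trials)
  acc <- accuracy_metrics(coll)

  agg <- stats::aggregate(
    cbind(disc_accuracy, signed_est_accuracy) ~ group + session, data = acc,
    FUN = mean, na.action = stats::na.omit)
  agg <- agg[order(agg$group, factor(agg$session, c("pre", "post"))), ]
  rownames(agg) <- NULL

  est <- coll[coll$task == "est", ]
  cells <- unique(est[, c("observer_id", "group", "stimulus_deg")])
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- est$observer_id == cells$observer_id[i] &
      est$stimulus_deg == cells$stimulus_deg[i]
    pre <- as.numeric(est$response[sel & est$session == "pre"])
    post <- as.numeric(est$response[sel & est$session == "post"])
    pre <- pre[pre > 0]; post <- post[post > 0]  # correct-side only
    if (length(pre) == 0 || length(post) == 0) {
      rows[[i]] <- data.frame(cells[i, ], auroc = NA_real_, p_value = NA_real_)
    } else {
      pt <- auroc_permutation_test(pre, post, n_perm = n_perm)
      rows[[i]] <- data.frame(cells[i, ], auroc = pt$auroc,
                              p_value = pt$p_value)
    }
  }
  auroc_tab <- do.call(rbind, rows)
  rownames(auroc_tab) <- NULL
  ok <- !is.na(auroc_tab$p_value)
  auroc_tab$significant <- NA
  auroc_tab$significant[ok] <- bky_fdr(auroc_tab$p_value[ok], q = fdr_q)

  cc <- acc[!is.na(acc$disc_accuracy) & !is.na(acc$signed_est_accuracy), ]
  r <- if (nrow(cc) > 2 && stats::sd(cc$disc_accuracy) > 0 &&
           stats::sd(cc$signed_est_accuracy) > 0) {
    stats::cor(cc$disc_accuracy, cc$signed_est_accuracy)
  } else NA_real_

  list(accuracy = acc, group_accuracy = agg, auroc = auroc_tab,
       accuracy_correlation = list(r = r, n_cells = nrow(cc)))
}
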