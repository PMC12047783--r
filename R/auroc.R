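#' Area under the ROC curve between two estimate samples
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly drawn
#' post-test estimate exceeds a randomly drawn pre-test estimate, with ties
#' counted 1/2. A value of 0.5 means complete overlap; values above 0.5 mean
#' the post-test sample is shifted toward larger values (further from the
#' horizontal boundary).
#'
#' @param pre_est,post_est Nonempty numeric samples (correct-side estimates).
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(1, 3), c(2, 4))  # 0.75
#' @export
auroc <- function(pre_est, post_est) {
  stopifnot(length(pre_est) > 0, length(post_est) > 0,
            is.numeric(pre_est), is.numeric(post_est))
  n1 <- length(pre_est); n2 <- length(post_est)
  r <- rank(c(pre_est, post_est))
  w <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  w / (n1 * n2)
}

#' Permutation test for AUROC
#'
#' Builds the null by swapping pre/post labels on the pooled sample
#' (preserving group sizes), and returns the two-tailed p-value for the
#' observed AUROC against 0.5, with the (b+1)/(n_perm+1) small-sample
#' correction.
#'
#' @param pre_est,post_est Nonempty numeric samples.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional RNG seed.
#' @return A list with `auroc`, `p_value`, and `null` (the permuted AUROCs).
#' @export
auroc_permutation_test <- function(pre_est, post_est, n_perm = 1000,
                                   seed = NULL) {
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  obs <- auroc(pre_est, post_est)
  pool <- c(pre_est, post_est)
  n1 <- length(pre_est); n <- length(pool)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n1)
    auroc(pool[idx], pool[-idx])
  }, numeric(1))
  b <- sum(abs(null - 0.5) >= abs(obs - 0.5))
  list(auroc = obs, p_value = (b + 1) / (n_perm + 1), null = null)
}

#' Two-stage adaptive FDR (Benjamini-Krieger-Yekutieli 2006)
#'
#' Stage 1 applies a Benjamini-Hochberg step-up at level q/(1+q) to estimate
#' the number of true nulls; stage 2 re-runs BH at the sharpened level
#' q/(1+q) * m/(m - r1), where r1 is the stage-1 rejection count. If stage 1
#' rejects nothing, nothing is flagged; if it rejects everything, everything
#' is.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Logical significance flags, same length as `pvals`.
#' @export
bky_fdr <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1), q > 0, q < 1)
  m <- length(pvals)
  if (m == 0) return(logical(0))
  q1 <- q / (1 + q)
  r1 <- sum(stats::p.adjust(pvals, "BH") <= q1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  q2 <- q1 * m / (m - r1)
  stats::p.adjust(pvals, "BH") <= q2
}
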