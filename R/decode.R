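#' Sample a Poisson population response
#'
#' @param pop A [build_population()] result.
#' @param s Stimulus direction, degrees (single value).
#' @param n_trials Number of independent responses to draw.
#' @return An `n_trials x n` integer matrix of spike counts; each neuron's
#'   count is an independent Poisson draw with mean given by its encoding
#'   tuning curve at `s`.
#' @export
sample_spikes <- function(pop, s, n_trials = 1) {
  stopifnot(inherits(pop, "tuning_population"), length(s) == 1L)
  rates <- encode_rates(pop, s)
  n <- length(rates)
  matrix(stats::rpois(n_trials * n, rep(rates, each = n_trials)),
         nrow = n_trials, ncol = n)
}

# Mean encoding rates at stimulus s (nearest grid point).
encode_rates <- function(pop, s) {
  i <- which.min(abs(pop$grid$values - wrap_angle(s)))
  pop$tuning_encode[, i]
}

#' Decode the likelihood over motion direction
#'
#' The decoder is unaware of the warp: log L(s) is the spike-count-weighted
#' sum of the logs of the *assumed* (homogeneous, pre-training-gain) tuning
#' curves, regardless of the session that generated the spikes. An all-zero
#' spike vector carries no information and yields a uniform likelihood.
#'
#' @param r Spike-count vector (length n), or an `n_trials x n` matrix for a
#'   batch.
#' @param pop A [build_population()] result (supplies `log_decode`).
#' @return For a vector `r`, a `likelihood_fn`: list with `grid` and `values`
#'   (non-negative, unit integral). For a matrix, an `n_trials x G` matrix of
#'   normalized likelihood rows.
#' @export
decode_likelihood <- function(r, pop) {
  stopifnot(inherits(pop, "tuning_population"))
  if (is.matrix(r)) return(decode_likelihood_batch(r, pop))
  stopifnot(length(r) == nrow(pop$log_decode), all(r >= 0))
  ll <- drop(r %*% pop$log_decode)
  v <- exp(ll - max(ll))
  v <- v / (sum(v) * pop$grid$step)
  structure(list(grid = pop$grid, values = v), class = "likelihood_fn")
}

decode_likelihood_batch <- function(counts, pop) {
  stopifnot(ncol(counts) == nrow(pop$log_decode))
  ll <- counts %*% pop$log_decode
  ll <- ll - ll[cbind(seq_len(nrow(ll)), max.col(ll, "first"))]
  v <- exp(ll)
  v / (rowSums(v) * pop$grid$step)
}

# Fast per-stimulus simulation core shared by simulate_block() and the loss:
# spikes -> unnormalized likelihoods -> discrimination (+ ties) -> optional
# conditional/unconditional estimates with motor noise. Normalization cancels
# in every ratio used, so it is skipped.
sim_stimulus <- function(pop, s0, n_t, task, conditional = TRUE,
                         sigma_m = 0) {
  counts <- sample_spikes(pop, s0, n_t)
  ll <- counts %*% pop$log_decode
  ll <- ll - ll[cbind(seq_len(n_t), max.col(ll, "first"))]
  v <- exp(ll)
  s_grid <- pop$grid$values
  cw_cols <- s_grid > 0
  ccw_cols <- s_grid < 0
  w_cw <- rowSums(v[, cw_cols, drop = FALSE])
  w_ccw <- rowSums(v[, ccw_cols, drop = FALSE])
  i0 <- which(s_grid == 0)
  half <- if (length(i0)) v[, i0] / 2 else 0
  d <- log_ratio_capped(w_cw + half, w_ccw + half)
  choice <- ifelse(d > 0, "CW", "CCW")
  ties <- which(d == 0)
  if (length(ties))
    choice[ties] <- sample(c("CCW", "CW"), length(ties), replace = TRUE)
  est <- NULL
  if (task == "est") {
    if (conditional) {
      mu_cw <- drop(v[, cw_cols, drop = FALSE] %*% s_grid[cw_cols]) / w_cw
      mu_ccw <- drop(v[, ccw_cols, drop = FALSE] %*% s_grid[ccw_cols]) / w_ccw
      est <- ifelse(choice == "CW", mu_cw, mu_ccw)
    } else {
      est <- drop(v %*% s_grid) / rowSums(v)
    }
    if (sigma_m > 0) est <- est + stats::rnorm(n_t, 0, sigma_m)
  }
  list(choice = choice, d = d, est = est)
}

# Per-row CW (s > 0) and CCW (s < 0) likelihood masses; grid mass at exactly
# 0 deg is split evenly (boundary evidence favours neither category).
side_masses <- function(values, grid) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  s <- grid$values
  cw <- values[, s > 0, drop = FALSE]
  ccw <- values[, s < 0, drop = FALSE]
  m_cw <- rowSums(cw) * grid$step
  m_ccw <- rowSums(ccw) * grid$step
  at0 <- which(s == 0)
  if (length(at0)) {
    half <- values[, at0] * grid$step / 2
    m_cw <- m_cw + half
    m_ccw <- m_ccw + half
  }
  cbind(ccw = m_ccw, cw = m_cw)
}

#' Discriminate from a likelihood: MAP category and log-evidence
#'
#' `d` is the log ratio of likelihood mass clockwise vs counterclockwise of
#' the boundary; the observer reports "CW" iff `d > 0`. Exact ties are broken
#' by a fair coin. `|d|` is capped at 700.
#'
#' @param L A `likelihood_fn` from [decode_likelihood()].
#' @param tie_seed Optional seed for the tie-break coin.
#' @return A list with `choice` ("CW" or "CCW") and `d`.
#' @export
discriminate <- function(L, tie_seed = NULL) {
  stopifnot(inherits(L, "likelihood_fn"))
  m <- side_masses(L$values, L$grid)
  d <- unname(log_ratio_capped(m[, "cw"], m[, "ccw"]))
  choice <- if (d > 0) "CW" else if (d < 0) "CCW" else {
    if (!is.null(tie_seed)) set.seed(tie_seed)
    sample(c("CCW", "CW"), 1L)
  }
  list(choice = choice, d = d)
}

log_ratio_capped <- function(num, den, cap = 700) {
  d <- suppressWarnings(log(num) - log(den))
  d[num == 0 & den == 0] <- 0
  pmin(pmax(d, -cap), cap)
}

#' Apply the lapse rule to a discrimination accuracy
#'
#' Aggregate accuracy is multiplied by `1 - lambda` and floored at chance:
#' `max(0.5, (1 - lambda) * p_correct)`.
#'
#' @param p_correct Accuracy in \[0, 1\] (vectorized).
#' @param lambda Lapse parameter in \[0, 1\].
#' @return Lapsed accuracy.
#' @export
apply_lapse <- function(p_correct, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("'lambda' must be a single number in [0, 1]")
  stopifnot(all(p_correct >= 0 & p_correct <= 1))
  pmax(0.5, (1 - lambda) * p_correct)
}

#' Conditional (post-categorization) Bayes-least-squares estimate
#'
#' The posterior is the likelihood times a conditional prior equal to 1 on the
#' chosen side of the boundary and 0 on the other; the estimate is the
#' posterior mean plus Gaussian motor noise.
#'
#' @param L A `likelihood_fn`.
#' @param choice "CW" or "CCW" (usually the implicit discrimination judgment
#'   on the same likelihood).
#' @param sigma_m Motor-noise SD in degrees (0 for the noiseless estimate).
#' @return The estimate in degrees.
#' @export
estimate_direction <- function(L, choice = c("CW", "CCW"), sigma_m = 0) {
  choice <- match.arg(choice)
  stopifnot(inherits(L, "likelihood_fn"))
  s <- L$grid$values
  keep <- if (choice == "CW") s > 0 else s < 0
  w <- L$values[keep]
  tot <- sum(w)
  if (tot <= 0) stop("degenerate posterior: no likelihood mass on the chosen side")
  est <- sum(s[keep] * w) / tot
  if (sigma_m > 0) est <- est + stats::rnorm(1L, 0, sigma_m)
  est
}
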