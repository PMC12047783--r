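# Shared fixtures, built in code.

# A mid-regime observer: visible warp, clear learning effect, small lapse.
ref_params <- function(lambda = 0, sigma_m = 2) {
  observer_params(warp_spec(a = 6, w_b = 20, sigma_b = 3),
                  g_pre = 5, g_post = 12, lambda = lambda,
                  shared = shared_params(sigma_m = sigma_m))
}

# One observer's full trial table (both sessions, both tasks, six directions),
# simulated through the mechanistic model; lapse expressed at trial level as
# in generate_study().
synth_observer_trials <- function(params = ref_params(), trials_per_dir = 60,
                                  seed = 1, grid_step = 0.5,
                                  observer_id = "S1", group = "est_train") {
  set.seed(seed)
  blocks <- list()
  for (ss in c("pre", "post")) for (tk in c("disc", "est")) {
    blk <- simulate_block(params, ss, tk, stimuli = c(-8, -4, -2, 2, 4, 8),
                          trials_per_stimulus = trials_per_dir,
                          grid_step = grid_step)
    tr <- blk$trials
    if (tk == "disc" && params$lambda > 0) {
      correct <- tr$response == tr$category
      flip <- correct & stats::runif(nrow(tr)) < params$lambda
      tr$response[flip] <- ifelse(tr$response[flip] == "CW", "CCW", "CW")
    }
    blocks[[paste(ss, tk)]] <- tr
  }
  tab <- do.call(rbind, blocks)
  tab$observer_id <- observer_id
  tab$group <- group
  tab$seed <- seed
  tab$trial_index <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

# Minimal single-cell trial table for statistics unit tests.
make_trials <- function(stim, est = NULL, choice = NULL, session = "pre",
                        observer = "O1", group = "est_train") {
  task <- if (is.null(est)) "disc" else "est"
  data.frame(observer_id = observer, group = group, session = session,
             task = task, stimulus_deg = stim,
             category = ifelse(stim > 0, "CW", "CCW"),
             response = if (task == "est") as.character(est) else choice,
             trial_index = seq_along(stim), seed = 0)
}

# Brute-force double-loop energy distance (independent oracle).
energy_oracle <- function(x, y) {
  2 * mean(abs(outer(x, y, "-"))) - mean(abs(outer(x, x, "-"))) -
    mean(abs(outer(y, y, "-")))
}

# Exhaustive pairwise AUROC (independent oracle).
auroc_oracle <- function(pre, post) {
  cmp <- outer(pre, post, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

# Independently coded two-stage adaptive FDR reference: explicit sorted
# step-up loops, no p.adjust.
bky_reference <- function(p, q = 0.05) {
  m <- length(p)
  step_up <- function(p, level) {
    o <- order(p)
    ps <- p[o]
    below <- which(ps <= (seq_len(m) / m) * level)
    r <- if (length(below)) max(below) else 0L
    flags <- logical(m)
    if (r > 0) flags[o[seq_len(r)]] <- TRUE
    flags
  }
  q1 <- q / (1 + q)
  r1 <- sum(step_up(p, q1))
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(p, q1 * m / (m - r1))
}
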