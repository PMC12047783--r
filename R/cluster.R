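#' Bin collapsed estimates into 5-degree direction bins
#'
#' Counts estimation responses in 5-degree bins spanning -70 to +70 degrees,
#' per participant and session (estimates are collapsed across directions
#' first, so a single histogram per participant x session). Bins are
#' left-closed, right-open, except the last which is closed; out-of-range
#' estimates are dropped (their number is recorded).
#'
#' @param trials A trial table (any stimuli; collapsed internally).
#' @param bin_width Bin width in degrees (default 5).
#' @param lim Range limit in degrees (default 70).
#' @return An object of class `binned_counts`: list with `edges`, `mid`,
#'   `counts` (array bins x participants x sessions), `group` (named vector,
#'   one label per participant), and `n_dropped`.
#' @export
bin_estimate_counts <- function(trials, bin_width = 5, lim = 70) {
  check_trials(trials)
  if (any(trials$stimulus_deg < 0)) trials <- collapse_by_category(trials)
  est <- trials[trials$task == "est", ]
  stopifnot(nrow(est) > 0)
  edges <- seq(-lim, lim, by = bin_width)
  nb <- length(edges) - 1L
  subj <- sort(unique(est$observer_id))
  sessions <- c("pre", "post")
  counts <- array(0L, dim = c(nb, length(subj), 2L),
                  dimnames = list(NULL, subj, sessions))
  x <- as.numeric(est$response)
  dropped <- 0L
  for (j in seq_along(subj)) for (k in 1:2) {
    sel <- est$observer_id == subj[j] & est$session == sessions[k]
    v <- x[sel]
    inr <- v >= -lim & v <= lim
    dropped <- dropped + sum(!inr)
    idx <- findInterval(v[inr], edges, rightmost.closed = TRUE)
    counts[, j, k] <- tabulate(idx, nbins = nb)
  }
  grp <- vapply(subj, function(s) est$group[est$observer_id == s][1],
                character(1))
  structure(list(edges = edges, mid = edges[-1] - bin_width / 2,
                 counts = counts, group = grp, n_dropped = dropped),
            class = "binned_counts")
}

#' Per-bin z-scores from a Poisson mixed (or conditional) model
#'
#' For each direction bin independently, tests whether estimate counts differ
#' between sessions across participants. The `"glmer"` engine fits the Poisson
#' generalized linear mixed model `count ~ session + (1 | participant)`
#' (Laplace ML) and returns the Wald z of the session effect (for
#' `design = "interaction"`, `count ~ group * session + (1 | participant)` and
#' the Wald z of the group:session interaction, group coded
#' trained-vs-control). The `"conditional"` engine uses the closed-form Wald z
#' of the equivalent participant-fixed-effect Poisson GLM in this balanced
#' paired design: z = log(P/Q) / sqrt(1/P + 1/Q) with P, Q the summed post/pre
#' counts (for the interaction, the log odds-ratio of session totals between
#' trained and control with the corresponding four-term variance). The
#' conditional engine is exact for the session contrast and is what the
#' permutation tests use (thousands of refits).
#'
#' @param counts A [bin_estimate_counts()] result.
#' @param design `"session"` (within-group pre vs post) or `"interaction"`
#'   (trained-vs-control x session).
#' @param engine `"conditional"` (default) or `"glmer"`.
#' @param trained_groups Group labels counted as trained for the interaction
#'   design (default everything except `"control"`).
#' @return A list with `z` (per-bin), `degenerate` (logical per bin: no
#'   counts, z set to 0), `design`, `engine`.
#' @export
glmm_bin_zscores <- function(counts, design = c("session", "interaction"),
                             engine = c("conditional", "glmer"),
                             trained_groups = NULL) {
  design <- match.arg(design)
  engine <- match.arg(engine)
  stopifnot(inherits(counts, "binned_counts"))
  a <- counts$counts
  if (dim(a)[2] < 2) stop("at least 2 participants are required")
  trained <- trained_group_mask(counts, trained_groups, design)
  nb <- dim(a)[1]
  if (engine == "conditional") {
    z <- vapply(seq_len(nb), function(i)
      conditional_z(a[i, , , drop = FALSE], design, trained), numeric(1))
  } else {
    z <- vapply(seq_len(nb), function(i)
      glmer_z(a[i, , ], design, trained), numeric(1))
  }
  deg <- apply(a, 1, sum) == 0
  z[deg] <- 0
  list(z = z, degenerate = deg, design = design, engine = engine)
}

trained_group_mask <- function(counts, trained_groups, design) {
  if (design != "interaction") return(NULL)
  if (is.null(trained_groups))
    trained_groups <- setdiff(unique(counts$group), "control")
  tr <- counts$group %in% trained_groups
  if (!any(tr) || all(tr))
    stop("interaction design needs both trained and control participants")
  tr
}

# Closed-form Wald z; a[i,,] collapsed to session totals. Haldane 0.5
# correction when a total is zero.
conditional_z <- function(slice, design, trained) {
  m <- matrix(slice, dim(slice)[2], 2)
  if (is.null(trained)) {
    q <- sum(m[, 1]); p <- sum(m[, 2])
    if (p + q == 0) return(0)
    if (p == 0 || q == 0) { p <- p + 0.5; q <- q + 0.5 }
    log(p / q) / sqrt(1 / p + 1 / q)
  } else {
    pt <- sum(m[trained, 2]); qt <- sum(m[trained, 1])
    pc <- sum(m[!trained, 2]); qc <- sum(m[!trained, 1])
    if (pt + qt == 0 || pc + qc == 0) return(0)
    if (any(c(pt, qt, pc, qc) == 0)) {
      pt <- pt + 0.5; qt <- qt + 0.5; pc <- pc + 0.5; qc <- qc + 0.5
    }
    (log(pt / qt) - log(pc / qc)) /
      sqrt(1 / pt + 1 / qt + 1 / pc + 1 / qc)
  }
}

glmer_z <- function(m, design, trained) {
  if (sum(m) == 0) return(0)
  ns <- nrow(m)
  df <- data.frame(count = c(m[, 1], m[, 2]),
                   session = factor(rep(c("pre", "post"), each = ns),
                                    levels = c("pre", "post")),
                   subj = factor(rep(seq_len(ns), 2)))
  if (is.null(trained)) {
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(count ~ session + (1 | subj), data = df, family = stats::poisson)))
    co <- summary(fit)$coefficients
    unname(co["sessionpost", "z value"])
  } else {
    df$grp <- factor(rep(ifelse(trained, "trained", "control"), 2),
                     levels = c("control", "trained"))
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(count ~ grp * session + (1 | subj), data = df,
                  family = stats::poisson)))
    co <- summary(fit)$coefficients
    unname(co["grptrained:sessionpost", "z value"])
  }
}

#' Cluster-mass permutation test on binned estimate counts
#'
#' Step 1: each bin gets a z-score ([glmm_bin_zscores()]); a bin is
#' significant if its z falls outside the two-tailed critical values taken
#' from that bin's own permutation distribution (or from the distribution
#' pooled across bins, if `pooled_critical = TRUE`). Step 2: maximal runs of
#' adjacent significant bins with the same effect sign form clusters whose
#' mass is the summed z; each observed cluster's two-tailed p-value is the
#' fraction of permutations whose largest absolute cluster mass reaches it
#' (with the +1 correction). Permutations swap the pre/post labels within,
#' never across, participants (for the interaction design, group assignments
#' are additionally permuted across participants).
#'
#' @param counts A [bin_estimate_counts()] result.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Two-tailed per-bin significance level for step 1
#'   (default 0.05).
#' @param seed Optional RNG seed.
#' @param design `"session"` or `"interaction"` (see [glmm_bin_zscores()]).
#' @param pooled_critical Use critical values pooled across bins
#'   (default FALSE: per-bin).
#' @param trained_groups See [glmm_bin_zscores()].
#' @return An object of class `cluster_result`: list with `z`, `crit`
#'   (per-bin lower/upper), `bin_significant`, `clusters` (data.frame:
#'   `from_deg`, `to_deg`, `sign`, `mass`, `p_value`, `sig_05`, `sig_10`),
#'   `null_mass`, plus the call settings.
#' @export
cluster_mass_test <- function(counts, n_perm = 1000, alpha = 0.05,
                              seed = NULL, design = c("session", "interaction"),
                              pooled_critical = FALSE, trained_groups = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(counts, "binned_counts"), n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  a <- counts$counts
  ns <- dim(a)[2]
  trained <- trained_group_mask(counts, trained_groups, design)

  zfun <- function(arr, tr) {
    nb <- dim(arr)[1]
    vapply(seq_len(nb), function(i)
      conditional_z(arr[i, , , drop = FALSE], design, tr), numeric(1))
  }
  z_obs <- zfun(a, trained)

  zperm <- matrix(0, n_perm, length(z_obs))
  for (p in seq_len(n_perm)) {
    swap <- stats::runif(ns) < 0.5
    ap <- a
    ap[, swap, ] <- a[, swap, 2:1]
    tr <- trained
    if (!is.null(trained)) tr <- sample(trained)
    zperm[p, ] <- zfun(ap, tr)
  }

  if (pooled_critical) {
    crit_lo <- rep(stats::quantile(zperm, alpha / 2), length(z_obs))
    crit_hi <- rep(stats::quantile(zperm, 1 - alpha / 2), length(z_obs))
  } else {
    crit_lo <- apply(zperm, 2, stats::quantile, probs = alpha / 2)
    crit_hi <- apply(zperm, 2, stats::quantile, probs = 1 - alpha / 2)
  }

  sig_obs <- z_obs < crit_lo | z_obs > crit_hi
  obs_clusters <- find_clusters(z_obs, sig_obs)
  null_mass <- vapply(seq_len(n_perm), function(p) {
    zp <- zperm[p, ]
    cl <- find_clusters(zp, zp < crit_lo | zp > crit_hi)
    if (nrow(cl) == 0) 0 else max(abs(cl$mass))
  }, numeric(1))

  if (nrow(obs_clusters) > 0) {
    obs_clusters$p_value <- vapply(obs_clusters$mass, function(m)
      (sum(null_mass >= abs(m)) + 1) / (n_perm + 1), numeric(1))
    obs_clusters$sig_05 <- obs_clusters$p_value < 0.05
    obs_clusters$sig_10 <- obs_clusters$p_value < 0.1
    obs_clusters$from_deg <- counts$edges[obs_clusters$from]
    obs_clusters$to_deg <- counts$edges[obs_clusters$to + 1L]
  } else {
    obs_clusters$p_value <- obs_clusters$sig_05 <- obs_clusters$sig_10 <-
      obs_clusters$from_deg <- obs_clusters$to_deg <- numeric(0)
  }

  structure(list(z = z_obs, crit = cbind(lower = crit_lo, upper = crit_hi),
                 bin_significant = sig_obs, clusters = obs_clusters,
                 null_mass = null_mass, n_perm = n_perm, alpha = alpha,
                 design = design, mid = counts$mid),
            class = "cluster_result")
}

# Maximal runs of adjacent significant bins with the same sign of z.
find_clusters <- function(z, sig) {
  lab <- ifelse(!sig | z == 0, 0L, ifelse(z > 0, 1L, -1L))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  data.frame(from = starts[keep], to = ends[keep], sign = r$values[keep],
             mass = vapply(which(keep), function(i)
               sum(z[starts[i]:ends[i]]), numeric(1)))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> design=%s, %d bins, %d permutations\n",
              x$design, length(x$z), x$n_perm))
  if (nrow(x$clusters) == 0) cat("  no clusters\n") else
    print(x$clusters[, c("from_deg", "to_deg", "sign", "mass", "p_value",
                         "sig_05", "sig_10")])
  invisible(x)
}
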