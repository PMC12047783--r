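# Mixture-based synthetic estimation trials for n subjects: pre draws from
# (mu_pos, mu_neg) mixture; post optionally shifts a share of the negative
# mass to the positive side (the learning signature).
mixture_trials <- function(n_subj = 7, n_trial = 120, w_neg_pre = 0.3,
                           w_neg_post = w_neg_pre, mu_shift = 0, seed = 1,
                           group = "est_train") {
  set.seed(seed)
  rows <- list()
  for (j in seq_len(n_subj)) for (ss in c("pre", "post")) {
    w <- if (ss == "pre") w_neg_pre else w_neg_post
    mu <- 15 + if (ss == "post") mu_shift else 0
    est <- generate_mixture_estimates(mu_pos = mu, mu_neg = -9, sd = 4,
                                      w_neg = w, n = n_trial)
    rows[[paste(j, ss)]] <- data.frame(
      observer_id = sprintf("M%02d", j), group = group, session = ss,
      task = "est", stimulus_deg = 4, category = "CW",
      response = as.character(est), trial_index = seq_len(n_trial), seed = seed)
  }
  do.call(rbind, rows)
}

test_that("binning is left-closed, conserving, and 28 bins wide", {
  tr <- mixture_trials(n_subj = 3, n_trial = 80, seed = 2)
  bc <- bin_estimate_counts(tr)
  expect_equal(dim(bc$counts)[1], 28)
  x <- as.numeric(tr$response[tr$task == "est"])
  expect_equal(sum(bc$counts) + bc$n_dropped, length(x))
  expect_equal(sum(bc$counts), sum(x >= -70 & x <= 70))
  # bin rule: 12.3 falls in [10, 15)
  one <- data.frame(observer_id = "A", group = "g", session = "pre",
                    task = "est", stimulus_deg = 4, category = "CW",
                    response = "12.3", trial_index = 1, seed = 0)
  two <- one; two$session <- "post"; two$response <- "15"
  b1 <- bin_estimate_counts(rbind(one, two))
  expect_equal(which(b1$counts[, 1, "pre"] == 1), which(b1$mid == 12.5))
  expect_equal(which(b1$counts[, 1, "post"] == 1), which(b1$mid == 17.5))
})

test_that("conditional z equals the participant-fixed-effect Poisson GLM Wald z", {
  set.seed(3)
  for (i in 1:5) {
    pre <- rpois(7, 8); post <- rpois(7, 12)
    slice <- array(c(pre, post), dim = c(1, 7, 2))
    z_pkg <- perclearn:::conditional_z(slice, "session", NULL)
    df <- data.frame(y = c(pre, post),
                     session = factor(rep(c("pre", "post"), each = 7),
                                      levels = c("pre", "post")),
                     subj = factor(rep(1:7, 2)))
    fit <- stats::glm(y ~ subj + session, family = stats::poisson, data = df)
    z_glm <- summary(fit)$coefficients["sessionpost", "z value"]
    expect_equal(z_pkg, unname(z_glm), tolerance = 1e-6)
  }
})

test_that("conditional z is close to the Poisson GLMM Wald z on populated bins", {
  tr <- mixture_trials(n_subj = 6, n_trial = 100, w_neg_post = 0.15, seed = 4)
  bc <- bin_estimate_counts(tr)
  zc <- glmm_bin_zscores(bc, engine = "conditional")
  zg <- suppressWarnings(glmm_bin_zscores(bc, engine = "glmer"))
  pre <- apply(bc$counts[, , "pre", drop = FALSE], 1, sum)
  post <- apply(bc$counts[, , "post", drop = FALSE], 1, sum)
  ok <- pre >= 5 & post >= 5
  expect_gt(sum(ok), 3)
  expect_lt(max(abs(zc$z[ok] - zg$z[ok])), 0.2)
})

test_that("per-bin z is calibrated under an exchangeable null", {
  set.seed(5)
  zz <- replicate(200, {
    slice <- array(rpois(14, 5), dim = c(1, 7, 2))
    perclearn:::conditional_z(slice, "session", NULL)
  })
  expect_lt(abs(mean(zz)), 0.1)
  expect_gt(stats::sd(zz), 0.85)
  expect_lt(stats::sd(zz), 1.15)
})

test_that("a constructed effect yields the largest z in its bin", {
  set.seed(6)
  base <- matrix(rpois(28 * 7, 5), 28, 7)
  a <- array(0L, dim = c(28, 7, 2), dimnames = list(NULL, 1:7, c("pre", "post")))
  a[, , "pre"] <- base
  a[, , "post"] <- base
  a[14, , "post"] <- 2L * base[14, ]
  bc <- structure(list(edges = seq(-70, 70, 5), mid = seq(-67.5, 67.5, 5),
                       counts = a, group = stats::setNames(rep("g", 7), 1:7),
                       n_dropped = 0L),
                  class = "binned_counts")
  z <- glmm_bin_zscores(bc)
  expect_gt(z$z[14], 0)
  expect_equal(which.max(abs(z$z)), 14)
  # single participant is degenerate
  bc1 <- bc; bc1$counts <- a[, 1, , drop = FALSE]
  expect_error(glmm_bin_zscores(bc1), "participants")
})

test_that("cluster test finds the learning signature in shifted mixtures", {
  tr <- mixture_trials(n_subj = 7, n_trial = 120, w_neg_pre = 0.30,
                       w_neg_post = 0.09, seed = 7)
  bc <- bin_estimate_counts(tr)
  cm <- cluster_mass_test(bc, n_perm = 300, seed = 8)
  expect_s3_class(cm, "cluster_result")
  sig <- cm$clusters[cm$clusters$sig_05, ]
  expect_gt(nrow(sig), 0)
  # a positive cluster where mass arrived (correct side)...
  pos <- sig[sig$sign > 0, ]
  expect_true(any(pos$from_deg >= 0))
  # ...and a negative cluster in the vacated incorrect-side region
  neg <- cm$clusters[cm$clusters$sig_10 & cm$clusters$sign < 0, ]
  expect_true(any(neg$to_deg <= 0))
  expect_true(all(cm$clusters$p_value >= 1 / (cm$n_perm + 1)))
})

test_that("interaction design separates trained and control groups", {
  tr_t <- mixture_trials(n_subj = 7, n_trial = 250, w_neg_pre = 0.35,
                         w_neg_post = 0.05, mu_shift = 6, seed = 9,
                         group = "est_train")
  tr_c <- mixture_trials(n_subj = 7, n_trial = 250, w_neg_pre = 0.35,
                         seed = 109, group = "control")
  tr_c$observer_id <- sub("M", "C", tr_c$observer_id)
  bc <- bin_estimate_counts(rbind(tr_t, tr_c))
  cm <- cluster_mass_test(bc, n_perm = 300, seed = 10,
                          design = "interaction")
  expect_gt(nrow(cm$clusters), 0)
  expect_true(any(cm$clusters$sig_05))
})

test_that("study-level summary ties estimation to discrimination accuracy", {
  set.seed(12)
  ids <- sprintf("P%02d", 1:10)
  rows <- list()
  for (i in seq_along(ids)) {
    prm <- sample_observer_params("est_train", seed = 400 + i)
    tab <- synth_observer_trials(prm, trials_per_dir = 15, seed = 500 + i,
                                 grid_step = 1, observer_id = ids[i])
    rows[[i]] <- tab
  }
  tr <- do.call(rbind, rows)
  s <- summarize_study(tr, n_perm = 120, seed = 13)
  expect_gt(s$accuracy_correlation$r, 0.4)
  expect_true(all(c("auroc", "p_value", "significant") %in% names(s$auroc)))
  expect_equal(nrow(s$group_accuracy), 2)
  # constant-accuracy degenerate input: correlation is missing
  cons <- make_trials(rep(4, 12), est = rep(5, 12))
  cons2 <- cons; cons2$session <- "post"
  consd <- make_trials(rep(4, 12), choice = rep("CW", 12))
  consd2 <- consd; consd2$session <- "post"
  s0 <- summarize_study(rbind(cons, cons2, consd, consd2), n_perm = 120)
  expect_true(is.na(s0$accuracy_correlation$r))
})
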