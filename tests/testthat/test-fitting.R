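test_that("energy distance matches the double-loop oracle and edge cases", {
  expect_equal(energy_distance(c(0), c(1)), 2)
  expect_equal(energy_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(4)
  for (i in 1:10) {
    x <- stats::rnorm(40, 0, 10)
    y <- stats::rnorm(37, 3, 5)
    expect_equal(energy_distance(x, y), energy_oracle(x, y),
                 tolerance = 1e-12)
    expect_gte(energy_distance(x, y), -1e-12)
  }
  expect_error(energy_distance(numeric(0), 1), "nonempty")
})

test_that("loss weights normalize both terms to 1 at theta_init", {
  tr <- synth_observer_trials(trials_per_dir = 25, seed = 31, grid_step = 1)
  dat <- observer_condition_data(tr)
  v <- make_variant("full")
  spec <- loss_spec(trial_budget = 150, grid_step = 2)
  th0 <- (v$lower + v$upper) / 2
  set.seed(9)
  l_raw <- behavioral_loss(dat, th0, v, spec, weights = c(1, 1))
  w <- 1 / attr(l_raw, "terms")
  set.seed(9)
  l_w <- behavioral_loss(dat, th0, v, spec, weights = unname(w))
  expect_equal(as.numeric(l_w), 2, tolerance = 1e-12)
  w_fun <- compute_loss_weights(dat, v, spec, theta_init = th0, seed = 5)
  expect_length(w_fun, 2)
  expect_true(all(is.finite(w_fun) & w_fun > 0))
  # different theta_init gives different weights
  w2 <- compute_loss_weights(dat, v, spec, theta_init = th0 * 0.6, seed = 5)
  expect_false(isTRUE(all.equal(unname(w_fun), unname(w2))))
})

test_that("behavioral loss: identical seed zero L1; degenerate weights; determinism", {
  tr <- synth_observer_trials(trials_per_dir = 25, seed = 32, grid_step = 1)
  dat <- observer_condition_data(tr)
  v <- make_variant("full")
  spec <- loss_spec(trial_budget = 120, grid_step = 2)
  th <- v$params_to_theta(ref_params())
  # data identical to one fixed model simulation, same seed -> L1 term exactly 0
  set.seed(77)
  mod <- perclearn:::simulate_condition_summary(th, v, spec)
  l <- behavioral_loss(mod, th, v, spec, weights = c(1, 1), seed = 77)
  expect_identical(unname(attr(l, "terms")["l1"]), 0)
  expect_identical(unname(attr(l, "terms")["energy"]), 0)
  # w_disc = 0 reduces the loss to the energy sum
  set.seed(3)
  l2 <- behavioral_loss(dat, th, v, spec, weights = c(0, 1))
  expect_equal(as.numeric(l2), unname(attr(l2, "terms")["energy"]))
  # identically seeded evaluations are bit-identical
  a <- behavioral_loss(dat, th, v, spec, seed = 12)
  b <- behavioral_loss(dat, th, v, spec, seed = 12)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("loss noise shrinks with the trial budget", {
  tr <- synth_observer_trials(trials_per_dir = 25, seed = 33, grid_step = 1)
  dat <- observer_condition_data(tr)
  v <- make_variant("full")
  th <- v$params_to_theta(ref_params())
  sds <- vapply(c(150, 600, 2400), function(budget) {
    spec <- loss_spec(trial_budget = budget, grid_step = 2)
    stats::sd(vapply(1:8, function(s)
      as.numeric(behavioral_loss(dat, th, v, spec, seed = s)), numeric(1)))
  }, numeric(1))
  expect_true(sds[3] < sds[1])
})

test_that("variants declare the right free parameters and mechanisms", {
  expect_error(make_variant("bogus"), "full, no_GC, no_BA, no_CI, TC")
  v_full <- make_variant("full")
  expect_length(v_full$free, 6)
  expect_true(v_full$conditional)
  expect_false(make_variant("no_CI")$conditional)
  expect_false("dg" %in% make_variant("no_GC")$free)
  expect_false("a" %in% make_variant("no_BA")$free)
  expect_true(all(c("A_tc", "sigma_tc") %in% make_variant("TC")$free))
  expect_false("sigma_tc" %in% make_variant("TC_reduced")$free)

  g <- direction_grid(1)
  # no_GC: pre and post populations identical
  v <- make_variant("no_GC")
  th <- c(6, 20, 3, 5, 0.02)
  expect_identical(v$make_pop(th, "pre", g)$tuning_encode,
                   v$make_pop(th, "post", g)$tuning_encode)
  # no_BA: encode curves use the identity warp
  vb <- make_variant("no_BA")
  pop <- vb$make_pop(c(5, 7, 0), "pre", g)
  expect_equal(sort(pop$preferred), sort(pop$anchors))
  # TC: post density gains bumps at the trained directions
  vt <- make_variant("TC")
  th_tc <- c(6, 20, 3, 5, 0, 30, 3)
  pre_pop <- vt$make_pop(th_tc, "pre", g)
  post_pop <- vt$make_pop(th_tc, "post", g)
  expect_identical(max(post_pop$gains), max(pre_pop$gains))  # gains tied
  expect_false(isTRUE(all.equal(pre_pop$preferred, post_pop$preferred)))
})

test_that("the evolution strategy minimizes a noisy bowl within budget", {
  set.seed(42)
  target <- c(0.3, -1, 2)
  fn <- function(x) sum((x - target)^2) + stats::rnorm(1, 0, 0.01)
  res <- es_minimize(fn, lower = c(-2, -2, -2), upper = c(3, 3, 3),
                     budget = 400)
  expect_lt(sum((res$par - target)^2), 0.1)
  expect_lte(res$n_eval, 400)
})

test_that("fit_observer returns the lowest-loss restart", {
  tr <- synth_observer_trials(trials_per_dir = 20, seed = 34, grid_step = 1)
  spec <- loss_spec(trial_budget = 100, grid_step = 2)
  f <- fit_observer(tr, make_variant("no_BA"), spec, n_restarts = 2,
                    budget = 40, seed = 8)
  expect_s3_class(f, "fit_result")
  expect_equal(f$best_loss, min(f$restart_losses))
  expect_length(f$restart_losses, 2)
  expect_s3_class(f$best_params, "observer_params")
})

test_that("cross-validation is stratified, frozen-weighted, and complete", {
  tr <- synth_observer_trials(trials_per_dir = 12, seed = 35, grid_step = 1)
  spec <- loss_spec(trial_budget = 100, grid_step = 2)
  cv <- cross_validate_models(tr, c("full", "no_GC"), k = 3, iterations = 2,
                              spec = spec, n_restarts = 1, budget = 40,
                              seed = 13)
  expect_equal(nrow(cv$folds), 2 * 3 * 2)  # variants x folds x iterations
  expect_length(cv$weights, 2)             # one frozen pair for all variants
  expect_true(all(c("full", "no_GC") %in% cv$summary$variant))
  expect_equal(cv$summary$delta_test[cv$summary$variant == "full"], 0)
  # a stratum smaller than k errors with its name
  idx <- which(tr$task == "est" & tr$stimulus_deg == 2 & tr$session == "pre")
  small <- tr[-idx[-(1:2)], ]
  expect_error(cross_validate_models(small, "full", k = 3, iterations = 1,
                                     spec = spec),
               "stratum")
})
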