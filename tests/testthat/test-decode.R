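test_that("spike sampling is Poisson with the tuning-curve means", {
  g <- direction_grid(0.5)
  p <- observer_params(warp_spec(0, 10, 2), g_pre = 10,
                       shared = shared_params(b = 5))
  pop <- build_population(p, "pre", g)
  set.seed(1)
  n <- 1e5
  counts <- sample_spikes(pop, 4, n)
  mu <- encode_rates(pop, 4)
  se <- sqrt(mu / n)
  expect_true(all(abs(colMeans(counts) - mu) < 3 * se))
  fano <- apply(counts, 2, stats::var) / colMeans(counts)
  expect_true(all(abs(fano - 1) < 0.05))
})

test_that("baseline-only population gives Poisson(b) for every neuron", {
  g <- direction_grid(1)
  p <- observer_params(warp_spec(0, 10, 2), g_pre = 1e-9,
                       shared = shared_params(b = 5))
  pop <- build_population(p, "pre", g)
  set.seed(2)
  counts <- sample_spikes(pop, 0.5, 1e5)
  expect_true(all(abs(colMeans(counts) - 5) < 0.1))
})

test_that("all-zero spike vector decodes to a uniform likelihood", {
  g <- direction_grid(0.5)
  pop <- build_population(ref_params(), "pre", g)
  L <- decode_likelihood(rep(0L, 10), pop)
  expect_equal(sum(L$values) * g$step, 1, tolerance = 1e-10)
  expect_equal(max(L$values), min(L$values))
})

test_that("likelihood equals the brute-force per-gridpoint product oracle", {
  # 3-neuron toy population with hand-set decode curves
  g <- direction_grid(1)
  curves <- rbind(2 + cos(g$values * pi / 180),
                  1.5 + sin(g$values * pi / 90)^2,
                  0.5 + exp(-((g$values - 30) / 40)^2))
  pop <- structure(list(log_decode = log(curves), grid = g,
                        tuning_decode = curves),
                   class = "tuning_population")
  r <- c(2, 0, 1)
  L <- decode_likelihood(r, pop)
  oracle <- curves[1, ]^2 * curves[3, ]
  oracle <- oracle / (sum(oracle) * g$step)
  expect_equal(L$values, oracle, tolerance = 1e-12)
})

test_that("discrimination is the likelihood-mass log ratio with tie-breaking", {
  g <- direction_grid(1)
  sym <- abs(sin(g$values * pi / 180))
  L <- structure(list(grid = g, values = sym / (sum(sym) * g$step)),
                 class = "likelihood_fn")
  res <- discriminate(L, tie_seed = 1)
  expect_equal(res$d, 0)
  set.seed(1)
  choices <- replicate(200, discriminate(L)$choice)
  expect_gt(mean(choices == "CW"), 0.4)
  expect_lt(mean(choices == "CW"), 0.6)

  v <- numeric(length(g$values))
  v[g$values > 0] <- 0.8 / (sum(g$values > 0) * g$step)
  v[g$values < 0] <- 0.2 / (sum(g$values < 0) * g$step)
  L2 <- structure(list(grid = g, values = v), class = "likelihood_fn")
  expect_equal(discriminate(L2)$d, log(4), tolerance = 1e-6)
  expect_equal(discriminate(L2)$choice, "CW")

  one_side <- ifelse(g$values > 0, 1, 0)
  L3 <- structure(list(grid = g, values = one_side / (sum(one_side) * g$step)),
                  class = "likelihood_fn")
  expect_equal(discriminate(L3)$d, 700)
})

test_that("lapse multiplies accuracy and floors at chance", {
  expect_equal(apply_lapse(0.9, 0), 0.9)
  expect_equal(apply_lapse(0.9, 0.1), 0.81)
  expect_equal(apply_lapse(0.6, 0.5), 0.5)
  expect_error(apply_lapse(0.9, 1.5), "lambda")
  expect_error(apply_lapse(1.2, 0.1))
})

test_that("conditional estimate is the chosen-side posterior mean", {
  g <- direction_grid(0.1)
  u <- ifelse(g$values > -90 & g$values <= 90, 1, 0)
  L <- structure(list(grid = g, values = u / (sum(u) * g$step)),
                 class = "likelihood_fn")
  expect_equal(estimate_direction(L, "CW", sigma_m = 0), 45, tolerance = 0.1)
  expect_equal(estimate_direction(L, "CCW", sigma_m = 0), -45, tolerance = 0.1)

  bump <- exp(-((g$values - 20) / 5)^2)
  Lb <- structure(list(grid = g, values = bump / (sum(bump) * g$step)),
                  class = "likelihood_fn")
  oracle <- sum(g$values[g$values > 0] * bump[g$values > 0]) /
    sum(bump[g$values > 0])
  expect_equal(estimate_direction(Lb, "CW", sigma_m = 0), oracle,
               tolerance = 1e-10)
  expect_error(estimate_direction(L3 <- structure(
    list(grid = g, values = ifelse(g$values > 0, u, 0)),
    class = "likelihood_fn"), "CCW"), "degenerate")
})

test_that("with identity warp, unconditional estimation is unbiased", {
  g <- direction_grid(0.5)
  p <- observer_params(warp_spec(0, 10, 2), g_pre = 8,
                       shared = shared_params(sigma_m = 0))
  for (s0 in c(-8, 4)) {
    pop <- build_population(p, "pre", g)
    set.seed(10 + s0)
    sim <- sim_stimulus(pop, s0, 1e4, "est", conditional = FALSE, sigma_m = 0)
    se <- stats::sd(sim$est) / sqrt(length(sim$est))
    expect_lt(abs(mean(sim$est) - s0), 3 * se)
  }
})
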