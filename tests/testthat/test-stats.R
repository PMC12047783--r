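test_that("collapsing negates downward trials and preserves correctness", {
  tr <- make_trials(c(-4, -4, 8), est = c(-12, 5, 20))
  cc <- collapse_by_category(tr)
  expect_equal(cc$stimulus_deg, c(4, 4, 8))
  expect_equal(as.numeric(cc$response), c(12, -5, 20))
  expect_equal(cc$category, c("CW", "CW", "CW"))

  d <- make_trials(c(-4, -4, 4), choice = c("CCW", "CW", "CW"))
  cd <- collapse_by_category(d)
  # correct/incorrect status is unchanged by collapsing
  expect_equal(cd$response == cd$category,
               d$response == d$category)
})

test_that("the downward sign-flip is an involution", {
  tr <- make_trials(c(-4, 2, -8), est = c(-12.25, 6.5, 3))
  once <- perclearn:::flip_downward(tr)
  twice <- perclearn:::flip_downward(once, which_rows = tr$stimulus_deg < 0)
  expect_equal(twice$stimulus_deg, tr$stimulus_deg)
  expect_equal(as.numeric(twice$response), as.numeric(tr$response))
  expect_equal(twice$category, tr$category)
})

test_that("signed estimation accuracy counts correct-side estimates", {
  tr <- make_trials(rep(4, 4), est = c(12, 9, -5, 14))
  expect_equal(accuracy_metrics(tr)$signed_est_accuracy, 0.75)
  expect_equal(accuracy_metrics(make_trials(rep(4, 3), est = c(1, 2, 3)))$
                 signed_est_accuracy, 1)
  expect_equal(accuracy_metrics(make_trials(rep(4, 3), est = -c(1, 2, 3)))$
                 signed_est_accuracy, 0)
  # boundary estimates are neither category
  expect_equal(accuracy_metrics(make_trials(rep(4, 4), est = c(0, 0, 5, 6)))$
                 signed_est_accuracy, 0.5)
  # empty cells are missing, not zero
  m <- accuracy_metrics(make_trials(rep(4, 2), est = c(5, 6)))
  expect_true(is.na(m$disc_accuracy))
})

test_that("AUROC matches its definitions and the exhaustive-pair oracle", {
  x <- c(3, 1, 4, 1.5)
  expect_equal(auroc(x, x), 0.5)
  expect_equal(auroc(c(1, 2, 3), c(4, 5)), 1)
  expect_equal(auroc(c(4, 5), c(1, 2, 3)), 0)
  expect_equal(auroc(c(1, 3), c(2, 4)), 0.75)
  set.seed(6)
  for (i in 1:60) {
    n1 <- sample(6, 1); n2 <- sample(6, 1)
    pre <- sample(seq(0, 5, 0.5), n1, replace = TRUE)  # ties likely
    post <- sample(seq(0, 5, 0.5), n2, replace = TRUE)
    expect_equal(auroc(pre, post), auroc_oracle(pre, post))
  }
  expect_error(auroc(numeric(0), 1))
})

test_that("AUROC permutation test detects a shift and bounds its p-value", {
  set.seed(8)
  pre <- stats::rnorm(30, 10, 3)
  # strong shift: small p for nearly all seeds
  small <- vapply(1:20, function(s)
    auroc_permutation_test(pre, pre + 10, n_perm = 200, seed = s)$p_value,
    numeric(1))
  expect_gte(mean(small < 0.05), 0.95)
  expect_true(all(small >= 1 / 201))
  # null: p is valid and not tiny for most seeds
  nulls <- vapply(1:20, function(s) {
    set.seed(100 + s)
    a <- stats::rnorm(30, 10, 3); b <- stats::rnorm(30, 10, 3)
    auroc_permutation_test(a, b, n_perm = 200, seed = s)$p_value
  }, numeric(1))
  expect_lt(mean(nulls < 0.05), 0.3)
})

test_that("two-stage FDR matches an independently coded reference", {
  p_fixed <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205,
               0.212, 0.216)
  expect_equal(bky_fdr(p_fixed, 0.05), bky_reference(p_fixed, 0.05))
  expect_equal(bky_fdr(rep(1, 8)), rep(FALSE, 8))
  expect_equal(bky_fdr(0.001), TRUE)
  set.seed(10)
  for (i in 1:50) {
    p <- stats::runif(sample(3:12, 1))^sample(1:3, 1)
    flags <- bky_fdr(p, 0.05)
    expect_equal(flags, bky_reference(p, 0.05))
    # monotone in p
    expect_true(all(diff(flags[order(p)]) <= 0))
    # on these inputs, at least as many flags as plain BH at the same q
    bh <- stats::p.adjust(p, "BH") <= 0.05
    expect_gte(sum(flags), sum(bh))
  }
})
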