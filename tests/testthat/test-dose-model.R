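test_that("dose grid enforces its invariants and defaults", {
  g <- dose_grid()
  expect_equal(g$actual_mg, seq(10, 80, by = 10))
  expect_equal(g$standardised, 1:8)
  expect_equal(g$period1_mg, c(10, 20, 40, 80))
  expect_error(dose_grid(c(10, 20), c(1, 2, 3)), "same length")
  expect_error(dose_grid(c(20, 10), c(2, 1)), "strictly increasing")
  expect_error(dose_grid(period1_mg = c(10, 15)), "subset")
})

test_that("inefficacy probability follows the one-parameter logistic curve", {
  expect_equal(inefficacy_probability(1, 5), 0.5)
  expect_equal(inefficacy_probability(0, 8), plogis(5), tolerance = 1e-12)
  # independent oracle: solve 5 - d = logit(0.05) for d, then evaluate
  d05 <- uniroot(function(d) inefficacy_probability(1, d) - 0.05,
                 c(0, 20), tol = 1e-12)$root
  expect_equal(d05, 5 - qlogis(0.05), tolerance = 1e-8)
  expect_equal(inefficacy_probability(1, d05), 0.05, tolerance = 1e-9)
  expect_error(inefficacy_probability(1, -1), "non-negative")
})

test_that("curve is strictly decreasing in dose for every supported slope", {
  g <- dose_grid()
  spec <- model_spec()
  for (b in seq(0.01, spec$beta_max, length.out = 25)) {
    p <- inefficacy_probability(b, g$standardised)
    expect_true(all(diff(p) < 0))
  }
})

test_that("backward fitting inverts the curve at unit slope", {
  expect_equal(backward_fit_standardised_dose(0.5), 5)
  expect_equal(backward_fit_standardised_dose(0.95), 5 - qlogis(0.95))
  # symmetry of p and 1-p around the intercept
  expect_equal(backward_fit_standardised_dose(0.05) +
                 backward_fit_standardised_dose(0.95), 10)
  expect_error(backward_fit_standardised_dose(0), "strictly inside")
  expect_error(backward_fit_standardised_dose(1), "strictly inside")
})

test_that("log-likelihood is the sum of per-record Bernoulli terms", {
  expect_equal(log_likelihood(trial_history(), 1.3), 0)
  h1 <- trial_history(1, 1, 50, 1)
  expect_equal(log_likelihood(h1, 1), log(0.5))
  set.seed(42)
  h <- random_history(8, n1 = 8)
  singles <- vapply(seq_len(nrow(h)), function(i)
    log_likelihood(h[i, ], 0.7), numeric(1))
  expect_equal(log_likelihood(h, 0.7), sum(singles))
  h_bad <- trial_history(1, 1, 15, 0)
  expect_error(log_likelihood(h_bad, 1), "not on the grid")
})

test_that("posterior masses are normalised for any history", {
  set.seed(101)
  for (n in c(0, 1, 5, 12, 20)) {
    h <- if (n == 0) trial_history() else random_history(n)
    post <- posterior_update(h)
    expect_equal(sum(post$beta_weights), 1, tolerance = 1e-9)
    expect_true(all(post$beta_weights >= 0))
  }
})

test_that("empty history returns the prior, with near-full-range 90% bands", {
  post <- posterior_update(trial_history())
  # uniform prior: posterior median of beta is the prior median
  expect_equal(post$beta_median, 5, tolerance = 0.01)
  wide <- post$per_dose$ci_hi > 0.9 & post$per_dose$ci_lo < 0.05
  expect_gte(sum(wide), 5)  # "most doses" span nearly [0, 1]
})

test_that("per-dose point estimates are strictly decreasing in dose", {
  set.seed(7)
  for (i in 1:10) {
    post <- posterior_update(random_history(10))
    expect_true(all(diff(post$per_dose$p_median) < 0))
    expect_true(all(diff(post$per_dose$p_mean) < 0))
  }
})

test_that("all-ineffective data pull the slope toward zero", {
  g <- dose_grid()
  doses <- c(rep(g$period1_mg, each = 2), rep(40, 10))
  h <- trial_history(1:18, rep(c(1L, 2L), c(8, 10)), doses, rep(1L, 18))
  post <- posterior_update(h)
  expect_lt(post$beta_median, 0.3)
  expect_gt(post$per_dose$p_median[8], 0.9)  # even 80 mg looks ineffective
  # fine-grid oracle at 10x resolution agrees
  fine <- posterior_update(h, model_spec(beta_points = 40001))
  expect_equal(post$beta_median, fine$beta_median, tolerance = 1e-3)
  expect_equal(post$per_dose$p_median, fine$per_dose$p_median,
               tolerance = 1e-3)
})

test_that("an extra effective response moves the slope median weakly up", {
  set.seed(2024)
  for (i in 1:100) {
    h <- random_history(sample(4:14, 1))
    post0 <- posterior_update(h)
    extra_dose <- sample(dose_grid()$actual_mg, 1)
    h2 <- rbind(h, trial_history(nrow(h) + 1, 2, extra_dose, 0))
    post1 <- posterior_update(h2)
    expect_gte(post1$beta_median, post0$beta_median)
  }
})

test_that("estimates are stable under quadrature refinement", {
  set.seed(314)
  spec2 <- model_spec(beta_points = 8002)
  for (i in 1:20) {
    h <- random_history(sample(0:16, 1))
    a <- posterior_update(h)
    b <- posterior_update(h, spec2)
    expect_lt(abs(a$beta_median - b$beta_median), 1e-4)
    expect_lt(max(abs(a$per_dose$p_median - b$per_dose$p_median)), 1e-4)
    expect_lt(max(abs(a$per_dose$p_mean - b$per_dose$p_mean)), 1e-4)
  }
})

test_that("credible intervals map monotonely from the slope interval", {
  post <- posterior_update(trial_history())
  # collapse the posterior to a point mass at beta = 1
  j <- which.min(abs(post$beta_support - 1))
  post$beta_weights <- replace(numeric(length(post$beta_weights)), j, 1)
  ci <- credible_interval(post, 50)
  # interval collapses to a point (0.5 up to the support-point resolution)
  expect_equal(unname(ci[1]), unname(ci[2]))
  expect_equal(unname(ci[1]), 0.5, tolerance = 0.005)

  prior <- posterior_update(trial_history())
  ci10 <- credible_interval(prior, 10)
  ci80 <- credible_interval(prior, 80)
  expect_true(all(c(ci10, ci80) >= 0 & c(ci10, ci80) <= 1))
  # higher dose: interval sits lower at both ends
  expect_lt(ci80[1], ci10[1])
  expect_lt(ci80[2], ci10[2])
  # near-total level approaches the image of the full support
  ci_full <- credible_interval(prior, 10, level = 0.9999)
  expect_lt(ci_full[1], 0.012)
  expect_gt(ci_full[2], 0.988)
  expect_error(credible_interval(prior, 10, level = 1.2), "level")
})

test_that("posterior serialises to JSON with model metadata", {
  post <- posterior_update(random_history(6))
  js <- jsonlite::parse_json(posterior_to_json(post))
  expect_equal(js$prior, "uniform")
  expect_equal(length(js$per_dose), 8)
  expect_equal(js$beta_median, post$beta_median)
})

test_that("degenerate updates and off-support priors are rejected", {
  expect_error(model_spec(prior = "exponential",
                          prior_params = list(rate = -1)), "positive")
  expect_error(model_spec(beta_max = -2), "positive")
})
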