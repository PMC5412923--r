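test_that("fixed-design enumeration matches the closed-form selection law", {
  or <- fixed_design_oracle(scenario1())
  p <- or$p_select["rule", ]
  # independent closed forms: selection needs a clean suffix and a failure
  # immediately below (binomial zero-failure probabilities per dose)
  expect_equal(unname(p["40"]), 0.95^5 * 0.99^5 * (1 - 0.25^5),
               tolerance = 1e-12)
  expect_equal(unname(p["80"]), 0.99^5 * (1 - 0.95^5), tolerance = 1e-12)
  expect_equal(unname(p["none"]), 1 - 0.99^5, tolerance = 1e-12)
  expect_equal(unname(p["20"]), 0.25^5 * 0.95^5 * 0.99^5 * (1 - 0.05^5),
               tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(or$n_ineffective, 5 * (0.95 + 0.75 + 0.05 + 0.01))
  expect_equal(or$n_below_target, 10)
  expect_equal(unname(or$n_per_dose[c("10", "20", "40", "80")]), rep(5, 4))
})

test_that("stochastic engine agrees with the enumeration oracle", {
  n <- 20000
  oc <- simulate_design(fixed_design(), scenario1(), n_realisations = n,
                        seed = 42)
  or <- fixed_design_oracle(scenario1())
  for (lab in colnames(or$p_select)) {
    p0 <- or$p_select["rule", lab]
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(oc$p_select["rule", lab] - p0), 3 * se + 1e-9)
  }
  expect_equal(oc$n_below_target, 10)  # deterministic allocation
})

test_that("selection probabilities are conserved and budgets respected", {
  oc_f <- simulate_design(fixed_design(), scenario1(), n_realisations = 200,
                          seed = 3)
  expect_equal(sum(oc_f$p_select["rule", ]), 1, tolerance = 1e-9)
  expect_equal(sum(oc_f$n_per_dose), 20)

  oc_a <- simulate_design(adaptive_design(0.05), scenario1(),
                          n_realisations = 20, seed = 3)
  for (cr in rownames(oc_a$p_select))
    expect_equal(sum(oc_a$p_select[cr, ]), 1, tolerance = 1e-9)
  expect_equal(sum(oc_a$n_per_dose), 18)

  # an all-effective scenario always yields a model selection, so the
  # confirmation cohort always runs and the budget rises to 20
  all_eff <- scenario("always effective",
                      setNames(rep(0, 8), seq(10, 80, 10)))
  oc_p3 <- simulate_design(adaptive_design(0.05, period3 = TRUE), all_eff,
                           n_realisations = 5, seed = 3)
  expect_equal(sum(oc_p3$n_per_dose), 20)
})

test_that("single-realisation selection probabilities are indicators", {
  oc <- simulate_design(fixed_design(), scenario1(), n_realisations = 1,
                        seed = 11)
  expect_true(all(oc$p_select %in% c(0, 1)))
  expect_equal(sum(oc$p_select["rule", ]), 1)
})

test_that("the same seed reproduces identical operating characteristics", {
  a <- simulate_design(fixed_design(), scenario1(), n_realisations = 300,
                       seed = 123)
  b <- simulate_design(fixed_design(), scenario1(), n_realisations = 300,
                       seed = 123)
  expect_identical(a, b)
  c2 <- simulate_design(adaptive_design(0.10), scenario1(),
                        n_realisations = 10, seed = 5)
  d2 <- simulate_design(adaptive_design(0.10), scenario1(),
                        n_realisations = 10, seed = 5)
  expect_identical(c2, d2)
})

test_that("no-target scenarios report no below-target count", {
  sc4 <- make_logistic_scenario(NA)
  oc <- simulate_design(fixed_design(), sc4, n_realisations = 50, seed = 2)
  expect_true(is.na(oc$n_below_target))
})

test_that("repeat stability: identical seeds give zero range, MC error shrinks", {
  z <- repeat_stability(fixed_design(), scenario1(), n_realisations = 100,
                        seeds = c(4, 4))
  expect_true(all(z$range == 0))
  set.seed(1)
  small <- repeat_stability(fixed_design(), scenario1(),
                            n_realisations = 200, seeds = 1:5)
  big <- repeat_stability(fixed_design(), scenario1(),
                          n_realisations = 5000, seeds = 1:5)
  # Monte-Carlo spread shrinks with more realisations per run
  expect_lt(mean(big$range), mean(small$range) + 1e-9)
  expect_error(repeat_stability(fixed_design(), scenario1(), seeds = 1),
               "two seeds")
})

test_that("operating characteristics serialise to JSON with metadata", {
  oc <- simulate_design(fixed_design(), scenario1(), n_realisations = 20,
                        seed = 9)
  js <- jsonlite::parse_json(oc_to_json(oc))
  expect_equal(js$design, "5+5+5+5")
  expect_equal(js$n_realisations, 20)
  expect_equal(js$metadata$method, "simulation")
  expect_equal(js$p_select$rule$`40`, unname(oc$p_select["rule", "40"]))
})
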