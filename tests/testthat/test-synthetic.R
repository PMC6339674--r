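test_that("sampled banks honour their design and are reproducible", {
  d <- simulation_design(n_items = 35, slope_range = c(2.4, 4.8),
                         threshold_range = c(-2.5, 0.6), seed = 1)
  bank <- sample_bank(d)
  expect_equal(n_items(bank), 35L)
  expect_true(all(bank$slope >= 2.4 & bank$slope <= 4.8))
  expect_true(all(vapply(bank$thresholds,
                         function(b) all(diff(b) >= 0.05 - 1e-12), TRUE)))

  # point slope range degenerates to a constant
  d3 <- simulation_design(n_items = 5, slope_range = c(3, 3), seed = 2)
  expect_equal(sample_bank(d3)$slope, rep(3, 5))

  # same seed, same bank; different seed, different bank
  again <- sample_bank(d)
  expect_identical(bank$slope, again$slope)
  expect_identical(bank$thresholds, again$thresholds)
  other <- sample_bank(simulation_design(n_items = 35, seed = 99))
  expect_false(identical(bank$slope, other$slope))

  expect_error(simulation_design(slope_range = c(-1, 2)), "positive")
  expect_error(simulation_design(extreme_target = 1.2), "extreme_target")
})

test_that("responses are deterministic under seed and extreme at extreme theta", {
  d <- simulation_design(n_persons = 50, n_items = 4, seed = 7)
  bank <- sample_bank(d)
  s1 <- simulate_responses(bank, d)
  s2 <- simulate_responses(bank, d)
  expect_identical(s1$rm$responses, s2$rm$responses)
  expect_identical(s1$theta, s2$theta)

  # theta far below every threshold: category 1 with probability ~ 1
  p <- prob_categories(bank$slope[1], bank$thresholds[[1]], -10)
  expect_gt(p[1, 1], 1 - 1e-6)
})

test_that("empirical category frequencies converge to integrated model probabilities", {
  # one item, a = 2, b = (-1, 0, 1, 2); oracle = numerical integration of
  # the category probabilities over the N(0,1) density
  bank <- item_bank("x", 2, list(c(-1, 0, 1, 2)))
  quad <- grm_quadrature(n = 301, range = c(-8, 8))
  marg <- colSums(quad$weights *
                    prob_categories(2, c(-1, 0, 1, 2), quad$nodes))
  n <- 50000
  d <- simulation_design(n_persons = n, n_items = 1, seed = 13)
  sim <- simulate_responses(bank, d, covariates = FALSE)
  freq <- tabulate(sim$rm$responses[, 1], 5) / n
  mc_se <- sqrt(marg * (1 - marg) / n)
  expect_true(all(abs(freq - marg) <= 3 * mc_se))
})

test_that("the extreme-pattern target is met by shifting the generating mean", {
  d <- simulation_design(n_persons = 5000, n_items = 35, seed = 17,
                         extreme_target = 0.077)
  bank <- sample_bank(d)
  sim <- simulate_responses(bank, d, covariates = FALSE)
  realized <- mean(apply(sim$rm$responses, 1,
                         function(x) all(x == 1L) || all(x == 5L)))
  expect_gte(realized, 0.06)
  expect_lte(realized, 0.095)
  # the model-implied expectation itself is within the calibration tolerance
  expect_lt(abs(expected_extreme_fraction(bank, sim$theta_mean_used) - 0.077),
            0.0055)
})

test_that("DIF injection shifts only the focal bank as constructed", {
  bank <- toy_bank()
  none <- inject_dif(bank, list(list(item = 2, group_variable = "g",
                                     focal_level = "f",
                                     uniform_shift = 0, slope_multiplier = 1)))
  expect_equal(none$focal$thresholds, bank$thresholds)
  expect_equal(none$focal$slope, bank$slope)

  shifted <- inject_dif(bank, list(list(item = 3, group_variable = "g",
                                        focal_level = "f",
                                        uniform_shift = 0.5)))
  expect_equal(shifted$focal$thresholds[[3]], bank$thresholds[[3]] + 0.5)
  expect_equal(shifted$focal$thresholds[[1]], bank$thresholds[[1]])
  expect_equal(shifted$reference$thresholds, bank$thresholds)
  expect_error(inject_dif(bank, list(list(item = "nope", uniform_shift = 1))),
               "unknown item")
})

test_that("without DIF the two groups' responses are exchangeable", {
  sim <- ability_like_sim(n_persons = 4000, n_items = 6, seed = 23)
  g <- sim$rm$covariates$gender
  # per-item category distributions agree between groups at large n
  for (i in seq_len(3)) {
    tab <- table(sim$rm$responses[, i], g)
    expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 1e-4)
  }
})

test_that("demographic labels approximate the target population proportions", {
  sim <- ability_like_sim(n_persons = 20000, n_items = 2, seed = 29)
  cov <- sim$rm$covariates
  expect_lt(abs(mean(cov$gender == "female") - 0.524), 0.015)
  expect_lt(abs(mean(cov$education == "middle") - 0.426), 0.015)
  expect_lt(abs(mean(cov$region == "west") - 0.496), 0.015)
  expect_lt(abs(mean(cov$ethnicity == "native") - 0.772), 0.015)
})
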