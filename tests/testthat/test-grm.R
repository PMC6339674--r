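test_that("category probabilities equal the cumulative-difference oracle", {
  a <- 2; b <- c(-1, 0, 1, 2)
  p <- prob_categories(a, b, 0)
  # independent evaluation of the cumulative logistic and its differences
  pstar <- c(1, 1 / (1 + exp(-a * (0 - b))), 0)
  expect_equal(as.numeric(p), pstar[1:5] - pstar[2:6], tolerance = 1e-12)

  # dichotomous item at its threshold splits 50/50
  expect_equal(as.numeric(prob_categories(1.7, 0.3, 0.3)), c(0.5, 0.5))

  # probabilities sum to one over a wide trait range
  theta <- seq(-8, 8, by = 0.5)
  expect_equal(rowSums(prob_categories(a, b, theta)), rep(1, length(theta)),
               tolerance = 1e-12)

  # limits: far left collapses onto the lowest category
  expect_equal(as.numeric(prob_categories(a, b, -30))[1], 1, tolerance = 1e-10)
})

test_that("item information matches its finite-difference construction and vanishes in the tails", {
  a <- 2.4; b <- c(-1.2, -0.3, 0.4, 1.7)
  h <- 1e-5
  for (th in c(-2, -0.5, 0, 1, 3)) {
    dP <- (prob_categories(a, b, th + h) - prob_categories(a, b, th - h)) / (2 * h)
    p <- prob_categories(a, b, th)
    expect_equal(item_information(a, b, th), sum(dP^2 / p), tolerance = 1e-6)
  }
  expect_lt(item_information(a, b, 40), 1e-8)
  expect_lt(item_information(a, b, -40), 1e-8)

  # additivity over items
  bank <- toy_bank()
  sep <- sapply(1:4, function(i) {
    item_information(bank$slope[i], bank$thresholds[[i]], 0.7)
  })
  expect_equal(test_information(bank, 0.7), sum(sep), tolerance = 1e-12)

  # information 1/0.316^2 gives reliability 0.90 on the theta metric
  se <- 1 / sqrt(1 / 0.316^2)
  expect_equal(round(reliability_from_se(se), 2), 0.90)
})

test_that("the marginal likelihood of a two-item toy matches brute-force quadrature", {
  # 2 dichotomous items, tiny n, independently integrated likelihood
  bank <- item_bank(c("d1", "d2"), c(1.2, 0.8), list(0.3, -0.4))
  X <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L), c(2L, 2L), c(1L, 2L))
  rm <- response_matrix(X, item_ids = bank$item_id, n_categories = 2L)
  fit <- fit_grm(rm, tol = 1e-5)

  nodes <- seq(-6, 6, length.out = 49)
  w <- dnorm(nodes); w <- w / sum(w)
  brute <- 0
  for (j in seq_len(nrow(X))) {
    lik_q <- rep(1, 49)
    for (i in 1:2) {
      lik_q <- lik_q * prob_categories(fit$bank$slope[i],
                                       fit$bank$thresholds[[i]],
                                       nodes)[, X[j, i]]
    }
    brute <- brute + log(sum(w * lik_q))
  }
  expect_equal(fit$log_likelihood, brute, tolerance = 1e-8)
})

test_that("EM recovers generating parameters and never decreases the likelihood", {
  d <- simulation_design(n_persons = 1000, n_items = 10, seed = 7)
  bank <- sample_bank(d)
  sim <- simulate_responses(bank, d, covariates = FALSE)
  fit <- suppressWarnings(fit_grm(sim$rm))

  expect_true(all(diff(fit$ll_trace) > -1e-6))
  expect_true(all(vapply(fit$bank$thresholds,
                         function(b) all(diff(b) > 0), TRUE)))

  a_err <- fit$bank$slope - bank$slope
  b_err <- unlist(fit$bank$thresholds) - unlist(bank$thresholds)
  expect_lt(sqrt(mean(a_err^2)), 0.35)
  expect_lt(sqrt(mean(b_err^2)), 0.15)
  expect_gt(cor(fit$bank$slope, bank$slope), 0.95)
  expect_gt(cor(unlist(fit$bank$thresholds), unlist(bank$thresholds)), 0.95)
})

test_that("ML scoring matches a dense grid search and clamps extreme patterns", {
  bank <- toy_bank()
  grid <- seq(-4, 4, length.out = 10001)
  set.seed(42)
  for (r in 1:100) {
    x <- sapply(seq_len(4), function(i) sample.int(5, 1))
    est <- score_theta(x, bank, "ML")
    ll <- rep(0, length(grid))
    for (i in 1:4) {
      ll <- ll + log(prob_categories(bank$slope[i], bank$thresholds[[i]],
                                     grid)[, x[i]])
    }
    expect_lt(abs(est$theta - grid[which.max(ll)]), 1e-3)
  }

  hi <- score_theta(rep(5L, 4), bank, "ML")
  expect_identical(hi$theta, 4)
  expect_true(hi$clamped)
  lo <- score_theta(rep(1L, 4), bank, "ML")
  expect_identical(lo$theta, -4)
  expect_true(lo$clamped)
})

test_that("EAP shrinks to the prior mean when the likelihood is flat", {
  flat <- item_bank("f", 1e-3, list(c(-1, 0, 1, 2)))
  est <- score_theta(3L, flat, "EAP")
  expect_lt(abs(est$theta), 1e-3)
  expect_equal(est$se, 1, tolerance = 0.01)   # posterior ~ prior
})

test_that("scoring error shrinks as the bank grows", {
  big <- ability_like_sim(n_persons = 150, n_items = 35, seed = 37)
  scores35 <- score_cohort(big$rm, big$bank, "ML")
  sub <- big$rm
  sub$responses <- big$rm$responses[, 1:8]
  sub$item_ids <- big$rm$item_ids[1:8]
  sub$n_categories <- big$rm$n_categories[1:8]
  scores8 <- score_cohort(sub, big$bank[1:8], "ML")
  ok <- !scores35$clamped & !scores8$clamped
  mae35 <- mean(abs(scores35$theta[ok] - big$theta[ok]))
  mae8 <- mean(abs(scores8$theta[ok] - big$theta[ok]))
  expect_lt(mae35, mae8)
})

test_that("category collapse recodes data onto the fitted bank", {
  # category 3 never observed
  X <- cbind(c(1L, 2L, 4L, 5L, 2L, 4L, 5L, 1L, 2L, 4L),
             c(1L, 2L, 3L, 4L, 5L, 1L, 2L, 3L, 4L, 5L))
  rm <- response_matrix(X)
  expect_warning(fit <- fit_grm(rm, max_cycles = 5), "collapsed")
  rec <- collapse_categories(rm, fit)
  expect_equal(rec$n_categories, c(4L, 5L))
  expect_equal(max(rec$responses[, 1]), 4L)
})
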