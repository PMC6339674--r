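test_that("the intercept-only fit equals the closed-form multinomial log-likelihood", {
  y <- rep(1:3, times = c(20, 30, 50))
  fit <- cumulative_logit_fit(y, NULL)
  expect_equal(fit$log_lik,
               20 * log(0.2) + 30 * log(0.3) + 50 * log(0.5),
               tolerance = 1e-12)
  expect_equal(fit$mcfadden_r2, 0)
})

test_that("a null predictor's coefficient is near zero at large n", {
  set.seed(73)
  n <- 10000
  theta <- rnorm(n)
  pr <- prob_categories(2, c(-1, 0, 1), theta)
  y <- 1L + rowSums(runif(n) > t(apply(pr, 1, cumsum)))
  x_null <- rnorm(n)
  fit <- cumulative_logit_fit(y, cbind(theta = theta, z = x_null))
  expect_lt(abs(fit$coefficients[["z"]]), 0.05)
})

test_that("the proportional-odds log-likelihood matches direct maximization on a toy set", {
  set.seed(79)
  y <- c(1, 1, 2, 2, 2, 3, 3, 1, 2, 3, 3, 3, 1, 2, 2, 3, 1, 2, 3, 2)
  x <- rnorm(20)
  fit <- cumulative_logit_fit(y, cbind(x = x))
  # independent brute-force maximization over (beta, zeta1, zeta2)
  negll <- function(par) {
    beta <- par[1]; zeta <- c(par[2], par[2] + exp(par[3]))
    eta <- x * beta
    cum <- cbind(0, plogis(outer(-eta, zeta, "+")), 1)
    p <- cum[cbind(1:20, y + 1L)] - cum[cbind(1:20, y)]
    -sum(log(p))
  }
  brute <- optim(c(0, -0.5, 0), negll, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(fit$log_lik, -brute$value, tolerance = 1e-6)
})

test_that("nested model log-likelihoods are monotone on real screens", {
  sim <- ability_like_sim(n_persons = 600, n_items = 6, seed = 83)
  res <- dif_screen(sim$rm, "gender", bank = sim$bank)
  expect_true(all(res$delta_uniform >= -1e-6))
  expect_true(all(res$delta_nonuniform >= -1e-6))
  expect_equal(res$delta_total, res$delta_uniform + res$delta_nonuniform,
               tolerance = 1e-10)
})

test_that("DIF-free data produce no flags; permuted labels stay below threshold", {
  sim <- ability_like_sim(n_persons = 1000, n_items = 10, seed = 89)
  res <- dif_screen(sim$rm, "gender", bank = sim$bank)
  expect_equal(sum(res$flagged), 0L)

  # permuted labels: statistically independent of everything
  set.seed(97)
  perm <- sample(sim$rm$covariates$gender)
  res2 <- dif_screen(sim$rm, perm, bank = sim$bank)
  expect_true(all(res2$delta_total < 0.02))
})

test_that("an injected uniform shift is flagged and classified as uniform", {
  d <- simulation_design(
    n_persons = 2000, n_items = 10, seed = 103,
    dif_spec = list(list(item = 3, group_variable = "grp",
                         focal_level = "focal", uniform_shift = 0.6)))
  bank <- sample_bank(simulation_design(n_items = 10, seed = 103))
  sim <- simulate_responses(bank, d, covariates = FALSE)
  res <- dif_screen(sim$rm, sim$rm$covariates$grp, bank = bank)
  expect_true(res$flagged[3])
  expect_equal(res$classification[3], "uniform")
  expect_equal(sum(res$flagged[-3]), 0L)
})

test_that("purification converges and keeps the injected flag", {
  d <- simulation_design(
    n_persons = 1200, n_items = 8, seed = 107,
    dif_spec = list(list(item = 2, group_variable = "grp",
                         focal_level = "focal", uniform_shift = 0.8)))
  bank <- sample_bank(simulation_design(n_items = 8, seed = 107))
  sim <- simulate_responses(bank, d, covariates = FALSE)
  res <- dif_screen(sim$rm, sim$rm$covariates$grp, bank = bank, purify = TRUE)
  expect_true(res$flagged[2])
  expect_lte(attr(res, "purification_iterations"), 10L)
})

test_that("age splits at the sample median with the boundary in the lower group", {
  g <- age_median_split(c(40, 53, 60))
  expect_equal(attr(g, "median"), 53)
  expect_equal(as.integer(table(g)), c(2L, 1L))

  same <- age_median_split(rep(50, 10))
  expect_equal(sum(same == "gt_median"), 0L)
  expect_error(
    dif_screen(ability_like_sim(n_persons = 100, n_items = 3, seed = 1)$rm,
               age_median_split(rep(50, 100))),
    "levels|floor|below")
})

test_that("group-size floors are enforced", {
  sim <- ability_like_sim(n_persons = 200, n_items = 4, seed = 109)
  tiny <- factor(c(rep("a", 195), rep("b", 5)))
  expect_error(dif_screen(sim$rm, tiny, bank = sim$bank), "floor")
})
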